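# Replication inputs: the published per-source gap-closure accounting rows and
# the lost-gene RGA 2x2 count tables, consumed by the replicate-tables stage.
seed: 1
replicate_tables:
  closure_rows:
    - {source: Unmapped_region_V1, count: 33, total_len: 28986}
    - {source: Singleton_BAC_Sequence, count: 3261, total_len: 1338596}
    - {source: PacBio_7DL, count: 6932, total_len: 3026326}
    - {source: Total, count: 8043, total_len: 3491264}
    - {source: All_gaps_census, count: 12825, total_len: 5798173}
  fisher:
    - {fg_hits: 12, fg_size: 53, bg_hits: 138, bg_size: 2917}
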