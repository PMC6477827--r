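# Example configuration: every key is optional and overrides the packaged
# default. Taxonomy pools are configuration, not code, so a corrected
# group-membership reading can be dropped in here.
taxonomy:
  pools:
    MonPalHen: [Mon, Pal, Hen]
    Stork_SPEC: [WhiStork, BlaStork]
protocol:
  window_minutes: {small: 10, large: 15}
  empty_pool_fallback: season_proportions   # or: skip, equal_split
  rare_flock_threshold: 5
  # overlap zones as [station-1 zone, station-2 zone] pairs
  overlap_zones:
    small:
      - [E2, W2]
      - [E2, W3]
      - [E3, W2]
      - [E3, W3]
      - [E4, W2]
      - [E4, W3]
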