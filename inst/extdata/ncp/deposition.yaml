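# Atmospheric N deposition: wet as concentration in rain (mg N/L), dry as
# annual totals (kg N/ha/y) spread uniformly over the year.
wet_nh4: 7.5
dry_nh4: 10.0
wet_no3: 2.5
dry_no3: 5.0
provenance:
  wet_nh4: literature
  dry_nh4: literature
  wet_no3: literature
  dry_no3: literature
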