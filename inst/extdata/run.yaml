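# Example run configuration tying a full analysis together.
care_models:
  - boa.yaml
  - ja.yaml
valuation: valuation.yaml
cohort: cohort.yaml
output_dir: "."
formats:
  - csv
  - json
scenario_mode: standard
log_level: info
seed: 20180101
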