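Drop a plain-text export of the archived intracellular dataset here as
dryad/<cell_id>/{train,validN}_{stimulus,voltage}.csv to enable the
real-data checks (see ?load_real). The repository ships no raw recordings.
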