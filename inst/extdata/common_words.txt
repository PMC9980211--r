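# Words overused in short responses to open-ended app prompts.
today
yes
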