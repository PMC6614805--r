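# data.table is used via :: only; this flag makes its [ dispatch work
.datatable.aware <- TRUE
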