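"sample_name","i5_barcode","i7_barcode","primer_name"
"u2os_bulk","TAGATCGC","AGCGGAAT","p323"
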