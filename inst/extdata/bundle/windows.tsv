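key	value
tpi_intron_window_start	211
tpi_intron_window_end	410
tpi_catalog_window_start	101
tpi_catalog_window_end	410
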