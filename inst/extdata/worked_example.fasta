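>worked_example tiny four-value discrete-scale text
CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD
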