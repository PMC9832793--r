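[{"name":"cont_01","kind":"continuous"},{"name":"cont_02","kind":"continuous"},{"name":"cont_03","kind":"continuous"},{"name":"cont_04","kind":"continuous"},{"name":"cont_05","kind":"continuous"},{"name":"cont_06","kind":"continuous"},{"name":"cont_07","kind":"continuous"},{"name":"cont_08","kind":"continuous"},{"name":"cont_09","kind":"continuous"},{"name":"cont_10","kind":"continuous"},{"name":"cont_11","kind":"continuous"},{"name":"cont_12","kind":"continuous"}]
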