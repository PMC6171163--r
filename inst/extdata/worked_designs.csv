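# Worked two-stage designs: rheumatoid arthritis, a prospective
# controls-rich design, and fronto-temporal dementia
n0,n1,n0p,n1p
20169,5539,8806,6768
15000,5000,5000,5000
4308,2154,5094,1372
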