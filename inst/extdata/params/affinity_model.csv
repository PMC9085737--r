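term,coefficient
ic_charged_charged,-0.09459
ic_charged_apolar,-0.10007
ic_polar_polar,0.19577
ic_polar_apolar,-0.22671
nis_apolar,0.18681
nis_charged,0.13810
intercept,-15.9433
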