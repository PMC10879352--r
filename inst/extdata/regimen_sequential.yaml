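# Sequential doxorubicin -> trastuzumab regimen (preset form).
# Equivalent explicit form: doxorubicin 60 mg/m2 IV (1 h) at weeks 0, 3, 6, 9;
# trastuzumab 4 mg/kg IV (1.5 h) at week 13 then 2 mg/kg weekly through week 65.
preset: DOX_then_TRZ
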