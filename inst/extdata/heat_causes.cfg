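# Diagnosis-code prefix -> heat-morbidity category.
# Categories: hyperthermia_heatstroke, dehydration, hyponatremia.
T67,hyperthermia_heatstroke
E86,dehydration
E87.1,hyponatremia
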