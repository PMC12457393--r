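green space
ecological restoration
public participation
punishment ladder
mandatory provision
supervision
fine
hearing
planning
protection
compensation
development
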