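["ATM", "BARD1", "BRIP1", "CDK12", "CHEK1", "CHEK2", "FANCL", "PALB2",
 "PPP2R2A", "RAD51B", "RAD51C", "RAD51D", "RAD54L"]
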