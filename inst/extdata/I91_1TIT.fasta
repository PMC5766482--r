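>I91_1TIT titin I91 (I27) domain, PDB entry 1TIT, 89 residues
LIEVEKPLYGVEVFVGETAHFEIELSEPDVHGQWKLKGQPLAASPDCEIIEDGKKHILIL
HNCQLGMTGEVSFQAANTKSAANLKVKEL
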