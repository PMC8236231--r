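>StDREB3_domain
PVYRGVRMRNSGKWVCEVREPNKKTRIWLGTFPTAEMAARAHDVAAIALRG
>StDREB12_domain
YRGIRMRKWGKWVAEIREPNKRSRIWLGSYSSPVAAARAYDTAVFYLRG
>StDREB63_domain
RYRGVRQRSWGKWVAEIREPRKRTRRWLGTFATAEDAARAYDRAAI
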