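>seed1 synthetic AP2 domain seed alignment member
YRGVRQRTNWGKWVAEIREPNKRSRIWLGTFDTAEEAARAYDVAAIALRGKFNF
>seed2 synthetic AP2 domain seed alignment member
YRGVRMRKNWGKWVAEIREANKKSRIWLGTFDPAEMAARAHDVAAIALRGRFNF
>seed3 synthetic AP2 domain seed alignment member
YRGIRQRSNWGKWVAEIREPNKRSRIWLGSFDTAEEAARAYDRAAIALRGKYNF
>seed4 synthetic AP2 domain seed alignment member
YRGVRKRTSWGKWVAEVREPSKRSRIWLGTFDTSEEAARAYDVRAIALRGKFDF
>seed5 synthetic AP2 domain seed alignment member
YRGVRQRNNWGKWVAEIRQPNKRTRIWLGTFDSAEEAARAYDVAAIALRGKFNL
>seed6 synthetic AP2 domain seed alignment member
YRGVRMRTNWGKWVAEVREPNRRSRIWLGTFDTAEDAARAYDVAAIALRGRYNF
>seed7 synthetic AP2 domain seed alignment member
YRGVRQRTDWGKWVAEIRDANKRSRIWLGTFDTSEEAARAYDVRAIALRGKFNF
>seed8 synthetic AP2 domain seed alignment member
YRGVRKRTNWGKWVAEIREPNKQSRIWLGTFDPAEEAARAYDVAAIALRGKFDL
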