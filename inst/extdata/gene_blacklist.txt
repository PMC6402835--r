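# Gene families excluded from recurrence calling (regular expressions matched
# against gene symbols). Families with high background mutation rates or known
# false-positive calls: titin, mucins, ryanodine receptors, dyneins, PCLO,
# cub/sushi-domain proteins, neurexins, contactins, PARK2, olfactory receptors.
^TTN$
^MUC[0-9]
^RYR[0-9]
^DNAH[0-9]
^DNAI[0-9]
^DNAL[0-9]
^PCLO$
^CSMD[0-9]
^NRXN[0-9]
^CNTN[0-9]
^PARK2$
^OR[0-9]+[A-Z]
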