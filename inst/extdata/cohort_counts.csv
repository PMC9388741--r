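variable,level,group,count
male,yes,none,13
male,no,none,10
male,yes,acute,10
male,no,acute,2
male,yes,chronic,14
male,no,chronic,4
tetraplegic,yes,acute,7
tetraplegic,no,acute,5
tetraplegic,yes,chronic,2
tetraplegic,no,chronic,16
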