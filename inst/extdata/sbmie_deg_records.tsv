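record_id	symbol	annotation
CI01000346_00033095_00038432	p53	tumor protein p53
CI01000071_04534337_04569325	mapk1	mitogen-activated protein kinase 1
CI01000026_10831971_10837028	f2	coagulation factor II, thrombin
CI01000004_11432849_11451784	yes1	proto-oncogene 1, Src family tyrosine kinase
CI01000010_02553536_02561950	zap70	zeta-chain (TCR) associated protein kinase 70 kDa
CI01000340_15454365_15456711	rspo4	R-spondin 4
CI01000010_05594817_05606739	abl2	proto-oncogene 2, non-receptor tyrosine kinase
CI01000325_02484476_02491983	kdr	kinase insert domain receptor
CI01000071_01149617_01177048	acacb	acetyl-CoA carboxylase beta
CI01000029_03698769_03707177	plg	plasminogen
CI01000059_06430220_06439547	casr	calcium sensing receptor
CI01000037_04313204_04343186	gsk3b	glycogen synthase kinase 3 beta
CI01000301_00660823_00677721	gsk3b	glycogen synthase kinase 3 beta
CI01000152_02905331_03070904	ephb1	EPH receptor B1
CI01100888_00000121_00001066	kdr	kinase insert domain receptor
CI01000339_02221790_02222160	p53	tumor protein p53
CI01000004_09490844_09498265	lyn	proto-oncogene, Src family tyrosine kinase
CI01022064_00000512_00000912	cdh3	cadherin 3
CI01000325_05045369_05061497	esr1	estrogen receptor 1
CI01000029_03746973_03752660	plg	plasminogen
CI01000001_00580789_00602408	src	proto-oncogene, non-receptor tyrosine kinase
CI01022123_00000351_00000764	cdh3	cadherin 3
CI01000054_01634335_01637623	rdh13	retinol dehydrogenase 13
CI01000051_03431193_03432454	jun	proto-oncogene, AP-1 transcription factor subunit
CI01072909_00000766_00002054	pcsk1	proprotein convertase subtilisin/kexin type 1
CI01000116_00002666_00003048	spink1	serine peptidase inhibitor, Kazal type 1
CI01000006_12380830_12394437	pcsk1	proprotein convertase subtilisin/kexin type 1
CI01000053_02118918_02119910	mos	Moloney murine sarcoma viral oncogene
CI01000339_02215633_02219758	p53	tumor protein p53
CI01000016_02328065_02334778	rdh13	retinol dehydrogenase 13
CI01022074_00000258_00000685	cdh3	cadherin 3
CI01000069_00059923_00065619	mapk3	mitogen-activated protein kinase 3
CI01000059_06430220_06439547_2	casr	calcium sensing receptor
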