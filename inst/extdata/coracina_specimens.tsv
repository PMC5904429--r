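specimen_id	species	sex	accession	locality	role
MF069139	S. coracina	male	MF069139	Iriomote Is., Okinawa, Japan	ingroup
MF069140	S. coracina	female	MF069140	Iriomote Is., Okinawa, Japan	ingroup
MF069141	S. coracina	male	MF069141	Samage, Weixi, Yunnan, China	ingroup
MF069142	S. coracina	female	MF069142	Samage, Weixi, Yunnan, China	ingroup
MF069143	S. coracina	male	MF069143	Mayanghe, Yanhe, Guizhou, China	ingroup
MF069144	S. coracina	male	MF069144	Mayanghe, Yanhe, Guizhou, China	ingroup
MF069145	S. coracina	female	MF069145	Mayanghe, Yanhe, Guizhou, China	ingroup
MF066953	S. fuscilimba	male	MF066953	Mengdong, Cangyuan, Yunnan, China	ingroup
MF066954	S. fuscilimba	male	MF066954	Mengdong, Cangyuan, Yunnan, China	ingroup
MF066955	S. fuscilimba	female	MF066955	Mengdong, Cangyuan, Yunnan, China	ingroup
MF066956	S. fusciventricula	male	MF066956	Menglun, Mengla, Yunnan, China	ingroup
MF066957	S. fusciventricula	male	MF066957	Menglun, Mengla, Yunnan, China	ingroup
MF066958	S. helvpecta	male	MF066958	Wuzhishan, Hainan, China	ingroup
MF066959	S. helvpecta	female	MF066959	Wuzhishan, Hainan, China	ingroup
MF066960	S. helvpecta	male	MF066960	Menglun, Mengla, Yunnan, China	ingroup
MF066961	S. helvpecta	male	MF066961	Likan, Ximeng, Yunnan, China	ingroup
MF066962	S. helvpecta	male	MF066962	Guanlei, Mengla, Yunnan, China	ingroup
MF066963	S. helvpecta	female	MF066963	Guanlei, Mengla, Yunnan, China	ingroup
MF066964	S. longispinata	male	MF066964	Menglun, Mengla, Yunnan, China	ingroup
MF066965	S. longispinata	male	MF066965	Menglun, Mengla, Yunnan, China	ingroup
MF066966	S. longispinata	male	MF066966	Menglun, Mengla, Yunnan, China	ingroup
MF066967	S. nigrolimbata	male	MF066967	Likan, Ximeng, Yunnan, China	ingroup
MF066968	S. nigrolimbata	male	MF066968	Likan, Ximeng, Yunnan, China	ingroup
MF066969	S. trivittata	male	MF066969	Mengdong, Cangyuan, Yunnan, China	ingroup
MF066970	S. trivittata	male	MF066970	Mengdong, Cangyuan, Yunnan, China	ingroup
MF066971	S. ventriobscurata	male	MF066971	Xincheng, Yingjiang, Yunnan, China	ingroup
MF066972	S. ventriobscurata	male	MF066972	Arboretum, Ruili, Yunnan, China	ingroup
MF066973	S. ventriobscurata	male	MF066973	Husa, Longchuang, Yunnan, China	ingroup
MF066974	S. ventriobscurata	female	MF066974	Xincheng, Yingjiang, Yunnan, China	ingroup
MF066975	S. ventriobscurata	male	MF066975	Wangtianshu, Mengla, Yunnan, China	ingroup
MF066976	S. zebrina	male	MF066976	Menglun, Mengla, Yunnan, China	ingroup
MF066977	S. zebrina	male	MF066977	Menglun, Mengla, Yunnan, China	ingroup
MF066978	S. zebrina	female	MF066978	Menglun, Mengla, Yunnan, China	ingroup
MF066979	S. zebrina	female	MF066979	Wangtianshu, Mengla, Yunnan, China	ingroup
MF066980	S. zebrina	male	MF066980	Wangtianshu, Mengla, Yunnan, China	ingroup
KR070820	S. maculata	unknown	KR070820	NA	outgroup
KR070823	S. melanogaster	unknown	KR070823	NA	outgroup
KR070829	S. nigricostata	unknown	KR070829	NA	outgroup
KR070838	S. obscurata	unknown	KR070838	NA	outgroup
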