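role_name	category	protein_seq
mosquito_actin	other	MGGINFFKAKIFVHSTPKTDPVQNNGRKCNTQEYDHLGEGYVDYYTVRGLPSPWQEKPFRELGYGSPDAGSAGAARSLETLPGPAELDCGDASQTQFWAFYTFKSRETPAEMNPLRRRSSVNKSLKPSLFLLMQNVMSINYIAPIGMFVLDETQRLEEDCQDEANTSLFFQEERTTIRVGQESWMTMADEAWAINSETRCDPAHVRASSGLGYVQQSGHLTFFLMTVQRSNAYEATMRFIGMRGLLPLEPHEWKKTIDLDVFRFALERHENVAFSAIDDVQKEAALAKEFIPRKKDLHVDKLLYGGVPKVTNKGEWIVETDITGKMIGHIEVLRKWGKTTAPFRPAITSGLNKTRVPVLYRAGSIKLSTSEDGLET
mosquito_histone_H3	other	MRYFTEFPQYFMLVAMLPLRYTLYMIQVLNQSEEASAINSIAPNILLREARRALNLSMRERSIYVSWIVANPQHSRLKGKNHPRGDAIRTEEGLVRASAIPVARRGFKAANTGAQAAADGHEKQDNNMAKTRAYVV
mosquito_tubulin_beta	other	MVTRLVLRYADNKQNERTSAMRFIGSNCDATGPVGWSAGLLELNKQGPWGNIMLGGLALNQRTMKDKKMINVFYVSDMRPLAVKKEITIVKEEGHINLVGGVIDKQQGLPKLAKLKLGEVGGKALTENMEVYNNSPHTSILGDGVALKIEAQLQQVDEVVEPTQACNFRLFGVGCYHTVFGVKYGMSFFTEDKEKLVRIQKSPIAVRVFLGIEALHGLKIWGEKFLVIPAAANGLLLFKTPTRLQVELVKPISLYCKVIRFGTKAQPKSMAGHRENIKKTPLDTVPLELILLEETDNNFAQRKISWANIDTHLVVPTAPKDVDAPGFISPKKDPRRPHALKVLNSTAKEVCYIITLLASKSHGALVHKIIFTGPIDDKWHELLHVFPDRLGTTCLGAKFIYEIGETSGPKKKRLRWNSMLPIVAAEVTVIKDVHVMKGALPAFPQAD
mosquito_ribosomal_P0	other	MELAGMLLSRSMKEFYDSVLGPWVVRPGILLAPGSRWANLDGLKLAELLHRMFKEIFLWRRCSQSTDTAGIAKDITFYDGGEVKAATFQGVLVIRRTTDWNTAGVAEPGHSTELYVLTSEVKLVHNLGENDGAHWTLLGTDKAMLAFITLYGPGYMHHWMPALVNRQNAKGILQITHKILMTSSDGSSEPLLARWPYERAVVIFPDSILTLTSYYTKPGLTSERRATMADRAVAMVIEEITSDFITAKITQDGKGANVENPWLDLLPHGVGMMYVQVYRLAREIPVNPSGLEDIQLSGFAKWGHILNIPDKTAKTEN
mosquito_vitellogenin	other	MDAWSLKGKLMEGDFIILKELRSPRLAVEMDRNQLEEWTAIRYRRHDVTIAREGAGKLKYVIKLHLQQLRQFLGRVFTYFKQINLYVMYLERDFDALRLNQPGSTAELTKLEFLATRMICALCEDLFAVVAQRANSARIGALELLRMRQSSSLAVEGYASALQTAELEGQRYEAGLLDGNVYAYAFQVLVSKIHTRAADTFEFRSIRTHGPANFRELRPQVSRDLIEEGIRHEVFMLDLDASLVGPLMAALVINGHCDDSRKYASFACVNSASRGRRIAVLLDFTDALYSLDSGLDNEFDFPVELQERSADSGDIPMEFLRKAMLRIHNAYSLKMRFKGIRNLKQNKPLALPLAGLLMPDRRGATLSPLYATLGGEFNARPGEFLAIYTEFRFFKTMELRALGGGSQILDEVPTQARLIQSLVTHASRSGNTNKIAQQQGGKDELVVSRI
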