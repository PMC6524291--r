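>mobile_capsid_1 class=phage label=capsid synthetic placeholder marker
MRLFALWLMPGQPSQVVIAVGWGWLRDENERYTPTSHEINSPDRAVGKCDNDYGSGTAAAGMEGCNQHNQFSADIWHFHE
LHWMAPFYPSQSATPKPERPYPEHAEYQKTLYRQYTPAPTEVRKHKETPDGKCQHPAIGTVPQSKWLKSNLVPRLCEYLK
IWPLTPLISDRMVTYESTEDAIHQQTNEPSITDLCFKKNKDMSAPTFHGHIKLTECSQFHSKKLGYKNYHRCWYTTTANS
IYNWCHCNTYAFGICPSNDYPIIFQRYMGNGGLKWGGGFVQHRNHRVLACEEWKHKVIIICFCHHNLITDRCAWDFRLWE
QRAREPVVGAKGHMGQSARPFEGVAEKFMSLAPWIRHTAWHCVLVYFCLYGDYPWFATYEGWTSMMFHVFGPQPVDDNME
TNVIPRSLSWYTWKTTG
>mobile_terminase_2 class=phage label=terminase synthetic placeholder marker
MKGAIWTHVVRPRDKFDIDMFCGYYCKLISAICLYRGDGGFNQKHHWNVAAAEDERQDIMNRWYAAWMGVVAQKRPSKLG
MITPFCWICVMDFDYTLCFEQPEWAMSCNVYPEAWVSSWYDCSLMHLEQSVEDRSQRLRHGMLPIIWPFYAPNQFHTTNN
CPWRPICDWCPGNHCIMLPTQGSWWRIIARSKNDNKVAPTGVEYNHCPCCQSIHISVTMVPYDAVLWWLNSCHCMCMFMC
CHTCYPANTSADTGQMGEMLFKGIQMNYCTDVICCYWQTGRHAETINFIMEYHHLWIWKDPSARKGRAGGPNFYSVFYIR
VDLTHWQIPKNANWRYDIDIVCDVNRHMMNNMRSSHPAGMQRCSYHWRLHFPDMYPCKAFWLNQYAQQWLVKGFDVSALF
FWF
>mobile_integrase_3 class=phage label=integrase synthetic placeholder marker
MMTSKWCHNDSPDKPSHPDEVEVSLQQCYLAWKKEGIWVPLCNPDTEMFARQQAMYTKVSMCMNGCHIFHAPIGNKHFTD
VYGSDPNTIVGCTKTIIEPQDPCSIAWQTAANWGWEEVMTRHVADVSQPVQCSQQEVMSNNCNQLFKEEEGGMFTKGAAV
LINLSDVKSNAESFIITGITCRTPEYFWFPNGFWHSYFEMMMEIILRLTLEGVCASYKLVFGSQWKFTLVRQSCMDLMEL
LSIVYPFWCSYPDTKWYMADSWVLTGMCNINSDPWQRCMEGCSGVRQVMFAWKSVQVIWYRSIERIYEAKNQGCWRVLVS
DCWYYKLPCEEQFKVHNFRYEYMVEQYCQDASGWPGNNVLQYAWQFLSFQSQFTHMAFYCWEKYTVYKHIPQKVDHDCWM
WLPWC
>mobile_portal_4 class=phage label=portal synthetic placeholder marker
MLMGWNRDKHMRVMCVTCECSVGYQCFMVCEWCCQMNILWDLITDYGYYVQLWLATNEKQSATNKNQHCMTARKTKDFLM
MPYSTTILATCFQHERVTERYFKGFDSICFWCKPPDFMAWSNFDKPQGRQRQHMTYILAWCCFGHHALFQHWQFHSDNQG
TFCFCWYVVSLNQSDQVHCQHDESQCKIPWPIELTQQKWCDTIGLNMYQNRNMQWIMPLKSSYATQIQGVWVCTHHRDTG
ISKHSAIYNELNAPCSRVIPPNIGYRGPDKICHWNLLAEVDCAKQCKFTAWIELAVTLWCWCEHAEVCTMHMYNMRVDMM
NIYPMPQTDHVWYMMGYISSRVNLENYVALYEVYWKPVMGTMKLMTSNFINVDKKVYADRF
>mobile_relaxase_5 class=plasmid label=relaxase synthetic placeholder marker
MAVWWQSDSSAQMYVSGVAYGGWQWWSQMVFQHHTIIVYRKTICSPYNEYYAETCLKKNLDVCWSLHVMYEWIMMKLCNA
ADLKWQYEPICEDDSHIQSNIWAKGYYFDRTQIFSGQKPWRTIIHHASEEMLVSNHKWGIENMMWWEWQIHAQWSASKVS
HLMIKWIELDCHCVQSYGQQNCWQHLVMELSMKIWDCFMCRQHNCIAEEGRTEYCDRPFMPVKCKMDQVCFETTCMGGTE
FAVHCARFWNALFTERQGPEDGSTPGLHIQCNHQRMWFVFELMMNCKEVKIIDSRNQKGIPWMMDDEFQEKAPNGCRWGD
GAFQSREDKADNGVCSPFSLMVCSCRVAYYICISKCKTWNSLDFFAECE
>mobile_mobilization_6 class=plasmid label=mobilization synthetic placeholder marker
MNPQWPHRRREHNCIKYWHDFIWWLQKQRIPMDYLCHLQHVQESTWMWVSASFIPVRGDMNYIQINTCKHNHHGECKLWQ
SQAQHQCKVWKPSLPEQWRIVPWHGDFWKQVRFYNKISNSKLWPQLHAFATAKGWFKINDVQMYCMVRQRNKLCCYDQLV
KNDCIMGNAIRYIFELKEVHRWIAIFHDKNVMDWSESGWVYESTNTQISLTRQCGETDGLCQVTDYAKIVTKYVKIENWE
DACRYFKYEWVKENMAVWRMTGQFIGGCNSCELGICAWHSYWTPVQRHKCGLGHFFFTKNNIGWGVGSSRFPDLHRGYWN
SEHTLEATPCPQRPQSIRFHKTEGCRVHGRLFSTYKQWMLGTLQF
>mobile_replication_initiator_7 class=plasmid label=replication_initiator synthetic placeholder marker
MWYAFNDCWVGYQVPCQLKFMENDNRAMKKFLIPTIFLTYLSLCFTRRSGSMGRPRITNMHNQSYEDFTYGCTTQNNEEK
IDVHARGQQGMVTLVFFLEKAMDCMILAQRQVCCYAWGRYGRRGSTMGQHNPGFEHKFILFMTYNCYTFNNCVDDFHHSW
LLNHAPHFQEFVCENNLGHSRQTLACCKDNDRMTTMLCHCSLIDCERLENTWTQLMKCGTSKMDTLHDPYFAYHLNIEHA
CNCEARHGVYKLKRMQECCNEWNMYHDMGEEPMEMDIVTFLKIAPMVQNNSEIYLKLKLPWLGMW
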