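>GH3_beta-xylosidase_1 family=GH3 label=beta-xylosidase synthetic placeholder exemplar
MPQHAHNYWENNQHFMQHCWHWFGQYEPAGLGFFDTFDEYTATDYSNVKHMEQPRWELVTEQNTWITPATVIECCDQMQD
NIYRPSVGIEDSRHIVVLPKGTDRFTWVFGSQDDTHEVELQFNPDEWVDTGIPGLHIGPADVPQTSFGRGRAKFSCNEKG
SCFCVDTKSNSCTTNMKYTKAHFFIIANEHPDWFPVERAIYPTDVSLRCSACDRRESSRGHGWYCNWLVKDYQYEVNFLG
KPERDRCYYDSDYPNENWVEKSGPAKRQIKFDTNGTAPKMEAFWNCEWYRSTWFQSQPLPQCMMNFKVKKEHYIVEQKQI
YGEITLVGSYQYGKSTFHILRMWFVDRHCFPMNYTMRVCDEISEQHQYEEFLMNDTHCEYWLHSRKMIMFLKHSMELAHH
ILCNVPTPAC
>GH3_beta-glucosidase_2 family=GH3 label=beta-glucosidase synthetic placeholder exemplar
MKNWPFAHDCYQMLEIRDFFIIYGYIFDKFQSPHSWYHFRYACTDGKSDWKPDYFRANGTERGTCPVDMAGACCCVKWGF
NVSQTISQRSDMNWEDQCVNMTYRHDKLTSSDPQDRDRTPNVPHRGSKRRRMHVTGRKVTPVITYKNENNWIHMGGKQVI
ESAWKDMELWGCDKDTAYNKSIAWHGKQCILLYCDQIFWMCLPKMMSQPKDEVQMQKQESHVLCEDYDDAPHNLHTKGRF
DKRVWYYAKCFWPLTFFADAALGQNACQRFNQEWGMVFMLFGRMAQKTLQFALFELGGQLCQCHIQLSRYRMMWMLEPKF
LELGIYENFGLEIKECAGWF
>GH10_xylanase_3 family=GH10 label=xylanase synthetic placeholder exemplar
MCAQCCMWFWSYRRCGQHKRDEMTSYDSHFCMKIMVVMTRDMVEKMVWPFRWFTTLQLDFDRHVICLLIDCFHYFCIWKH
NSKYHESQYNEHSYQHHIMNNSSLHFFGDCCCYCNSHDEIAFEPALWPIPGESWGVGIGCGTVERQNNDGTRVMGGLAAL
QRGSIMSAYQREEGEMQITYSCATHPLTCRWRSFACHHRDRPLVRKYMLNEKVKNYFIGVDISMRYCIWNMPRGKFIPCA
THANRAKLWHFHHRFDSDQISYSFYWWGYWYDAKRDMYQHCLTNVNMNLGPSRERPFPSWHLEIDANVLQEYPNDAWMSR
CIAIIGMRAWHWTAQIRLTCRGWNEPFKWVHGTNLIQSHDEWIDH
>GH11_xylanase_4 family=GH11 label=xylanase synthetic placeholder exemplar
MKFHLWEVLEHNMNAKVYQCTQCMVVAWAIFTWPHKAYCLSGNKHIYDKVSRTWANHLKAKCNCREWWQRNAVGCPRGFE
TYYITIDRKHCKMQFTWIGKKYHIVHKLSMITHPGVWFTNVHYPILAGYMDESQTGTNRQSIYAMIPHGSCDEAIRDKPA
RPVQTKHMGGDDVPRAIWCVLRNNTQFQYCYWVAGAITYNKHKLPYAFKCRMEGFNPKTWKYFFDYQGECNWNCPSLMFE
HKCEQVQHATVDWFACYGKWGAPPHVMLGGNFIGLNWSHQLDCKPFEEFAQVYWYINMNYEYDHYLFAWYTCQSDFRFYW
WMYEKVQYFFDHIEKMGFSEYCSWYRTCYLCSIKFFCPGSQWMFNDCSFQYYASKKYIQHANNDFDQLNY
>GH13_pullulanase_5 family=GH13 label=pullulanase synthetic placeholder exemplar
MWKQTDDQNYDGGHLVQMAFRELRRYADHYPGCCIGYLPHGYWADQCPQIIWGHAAKIDARRWIKEYQLNHRNINCQFTV
TVHMGHIWYNCHWSSLGVFKVELGQFSNHPMHDSWGANWRIVYGFTGKWVEWVNYHYTRDTIHSKWIPMDMHASGWFLWE
HQGVCFTTFAHRHERYEPEAWGITWPDQRHWWADDKHTCGDHTMKTIWYNMKMFSINVEDYTRIKPCERRAVTHAHVFCF
AIRAMFECGFHFHRDHTLGFFAIMLEILPRSQFFIQIELGYVPASTMADIKQWWGVYRWGMAVKSQVMNWKMTYQCRGHF
DYKQRERFVNREILEMVANVEYQCKNNCDINWQSQCYCEYRAEAMQEASEALYYMSKTPQYSELEWRFINKVLFMFAQAI
MNM
>GH13_amylase_6 family=GH13 label=amylase synthetic placeholder exemplar
MLDQLGLNHPPSPGQDRKYFLHRLHVNSLSVCWWMFWYMPDTYEHWMDHHNRHYFFICAHVEANDYAASVRHHDSLGEPF
DCDQRLFSDPLMGFKIESEGKWIIVDWSLVLGTDMDRWALKWGYNMQGGDMTYADYFMNWLQKGNVNDTDEWPWAQAHMY
QEMNQCSFSMLDQMKPILHKTYMANNIREYHQFFKQMLCDWICSAWRHINVDHNQMEDGSDDKFMWKEFWFCAGEDAWNF
TSCCCMNKGVDHVELIINTWIETMSWPWINNYKSIVFAMCCFCKDGNPITGTFHLNVYNTEHGHTAVTPSWGLPKRCDDD
EKHKMW
>GH43_beta-xylosidase_7 family=GH43 label=beta-xylosidase synthetic placeholder exemplar
MADNMACEAFEGPEADHRNDNLVHLKSKETWSAVWEPYPMEVGIMHNMRALLEHFQGKNNLVCTLYMCEPGILNDVIKPS
DHYLLDPKIAFTQAIGYWFTWCEGIYHRLTKPYQQDCLYMECWMWECMWSFPSIHYDEAVMIENEETNCPELDRANVPCW
AKTMFYSHWHNGHTPLNWDCEACTTTACQSNYKGWYCWLPAIQKAMGLILNYSWSTYADQYDFNEMQLGCVSAQCMGPEC
RLNRPWSWEHYDPTFHFYVWGPPYKEYCMMRNCVLRKLCQCIIGDTIKFLYTPHMHMRTIPKLTNEKKRTAAKQSCYCGA
WCPWTVIHWHDHPLWIFWESRAGWFNNPWLGGELFTTGNMNNVDLDAADWDCKNKIMSAEPSHMFVEFSCWIMKWSG
>GH43_arabinofuranosidase_8 family=GH43 label=arabinofuranosidase synthetic placeholder exemplar
MIWEVFEPMPIQGYTAEKSCRIFVQPNANWCWDMSGCQHFMMGAMASCVDKLRQSQFVASPLIHRATPKHRNKCDVTKHA
KMMMTQRFYLKRRWWFSAYYAMWYALYLCWDEWKWHREQEYPKFVKNNQKNTMTCTATSLGGYQNMLMPCAPAGKVARRW
LIESESPALMRDDINSCSWRIHPLRIYHFVGILETLKHSPKNLWYSIHIASKLDARQFGWCCWNMDKHSRGTMFDNVKTV
QIVSEWPFHICTNRAYTGCNERINIHNGYRLQPLASVCWRENEKKSVHNWFRHTTLHNRLGVYGDYQMRWFPNSNWKQSQ
RVEREKHCVQCFEIDSICVCPTRLMGPIRYRFVHMKWDMCHMWKTKHWVMHQMNYRDDAFPSIGNGK
>GH53_galactanase_9 family=GH53 label=galactanase synthetic placeholder exemplar
MNQQLDCWSMMFSCATTKKQNPISGHGECLHFNNPNRAPVCLCLGNCCYQRQGSVSVHGMLLQNDVSWYHYQFGVNYADC
YNFPVIQDCHVCDDLYMKTIYGYNIMPVGKKIEEKIRFKKRTMDRAQLQYMTQGTLWEVAEMNTNAQRSTIDGDDMLIWR
NVYNSPFCLCTQRKFPTTVVHAQDFPKKNMCMFLFTYWNLRVICLEMQYENDKQRLHQICHTCLAAARDVPYENKDRCET
MCIMADPHVQTRNRIAQYGMPKEGRKQWKEDCDKFTMVNHRGQELMTSSLPPWTWHAKEVQAWPMDRVEINMYFKFEVLR
DKNQVIDDMAMFWDIMTYAYWISCELKTMTRDGMIVPVDLWEVGLSPNKADYTNSILITKRQLQFEATMLVKIARMKNVQ
HMNRTLFSDQYVAQFCHEAFIPCDTRVPG
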