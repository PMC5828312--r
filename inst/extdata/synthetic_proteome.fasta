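>synthetic_protein_001
ATGGNATLDLCVPSWYWLPTCVRSGGEQTNQTNEIEYVLQYMDINPIEAGESGKIRKPTTVESDQPADTEPHFFGIELAI
VEVLYGIDKVQGETTEPVMLNGRELIPPDNGQKTDGRVIAPAFNNKFPYNINRKGDSIGHLMAYGGSNTNWQPQKRKKVN
GEVNVIEILTICMSSHIIDLNSSIFRLEVYEERFITTFALPTLEQKQVNIKSVPRIIGISGYHMAEFEQLPKLAHIITER
NSHLRIKVLRQESGNSNSPKFKGRREQHDEQVLQGEDLDGRSTTGVRIPLADVPFVGAESIDGQLQFQFETQPMKAKHNP
QVVYPPIEPSLVLERGFTAEIRDVNLYVDESACHWKFIEERASGFLRELASELRFFEVAVTFPTGKTGSAITCPNYTLIA
FEAQSMPALTFNKNLNSYSNGHHGTVKLAVVAELATQGRDSAYATGGEVLLRQYSEKLEFNNLEDGLQNMVLVTDAASHF
VCCSSLTSLGNSLTLGLRETVASMSWMATSDNGHLSWSQNQFRSSNKRGPYRNEPTENAADKWEQQNGYAYACTINLASR
KTSNDQRKESQFSTMTAFTDLPKKETGFLFSTRAENKDVDVWAEMYETAEFLQDYSMALLILFSPKARVQLHALSYWRKA
NTSCDISQASSGINETQFDRTGGYANQKKFFGGAACLPLNGDFIFGDAKLRGRGTTLLNDVMVASRLTGPWTDHLLTRKF
IESAPNIVCDQGLRQVRRESNGAQRWDQQMLDLCWSPCILETDRLPQNALELGKDEGGSHDPPIITARGPQVVTFNSAYS
HINLRSHWTELVEVLTIEDNKEIAADPAEGGELDIVTL
>synthetic_protein_002
PRNVSTMPVNELNILGEHWLDSTMKIKEQINANAAGAELSHAKCRGKEQFCGLAPGMRAVITKTEPDNDTGLGSQESYGE
CEDVDTELSCIKARPHLEKTLTGWVTPDGELNAYQLFDDLTQYYKTHVEYAAHGLHQQMVNEQSCSYQGGSLTGESTAPL
SVACRYGIVAAGGEAFIRSLVQDNVTSSNLDPYLGNADGSWSGPFKQYLKTTASNAGSLESVTSTIELEDYFQIHAEEKL
WTFHSANKQTKSRTADEYRFRVVTCWQGMNRKKLSGKSGEEHARAMLCISPVQGAVPIRKGPKVSPLSSIYMSRV
>synthetic_protein_003
ISVFDDCSIQTAGPAFKTVHKLDFKDIRTFRGKVKCHLVPDRPANWGEQCVSHSPYRLIITDLFISLFQIGMEGPSQLTD
TKQADSAQGLFANGQLANLKTFAKSVAGKPLSAANGCKVLILGKTLGGVSTQMQIAKRQFQISITHGFDLPKSESEINKA
TKESLYGWGLTGVTGALCRPVNLGFFPQACFESATDTQYRLGFPSLPWHSPEGAYLEKQAQDTILLFAWLILAPSEDLIL
LLVAATSKPSRTRQAASLDTGQPGNVGEVKTKIGPWVNECVSQVQCIPYAEIIITVIKFYWSIAPVAGRLTTAFCILIPF
LSNHVGTGLKKVTYHFHSTLVGTTAVESRIQIGRLSHRAGVMLPKSEQVQPIAILQHNPEQLRLSTSEEFD
>synthetic_protein_004
TVIDFNAMKIKCSLLATIAGNLAQSDSASGQNNSNLMEIGFDQSEWTATSTEAYQKNASSVDSYAVFYDFKCRIEEVPLV
KVSHDSEMKLCDTKASGAKKLLVLALRLCEVPIKLYPSADQLSSKAALGDSLGMDPYGFSSHMENFPFAKQDGSLSQVGD
IKCSAEVVDHLWKGFADELTVTDLEIEFTVIDLFLEEGGSAELVTVHCLFANTMLTKPACCRTESLALASLEPKRIGHFY
TELHNNTFMQTQRSSGQRPSTTFSPGGPFGDTHNRIKIEWYAKNSLEIRIDADRYISIRLSIPPGAWGVRVAEKQALGEH
PNKCIAMVTENFCEGCDNKTTLGGVKTYFAVNAAEEADPMALFNNQDVFDGEFPSKTGLPVEGVVGVDSRRRFNSDLLQK
PNEYHALQYHYQGRDNVEGLIAALLGSLQQLLT
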