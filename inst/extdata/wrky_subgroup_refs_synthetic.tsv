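id	subgroup	sequence
IIa_ref1	IIa	WRKYGQKKMRSFTCTFLQCYISDGDLRLIDQVSKTSAELYIHIH
IIa_ref2	IIa	WRKYGQKKMRSFSCTFLQCTISDGDLRLIDQVSKTSAELYIHIK
IIa_ref3	IIa	WRKYGQKKMRSFTCTFLQCKISDGDLRLIDQVSKASAPLYIHIH
IIb_ref1	IIb	WRKYGQKTPITLNCLQMLCVDQQQELLPNRSEKQKRMTDDTHQH
IIb_ref2	IIb	WRKYGQKTPITLNCLQILCVDQQQELPPNRSEKQKRMEDDTHQH
IIb_ref3	IIb	WRKYGQKTPITLNCLQMLCVDDQQELFPERSEKQKRMTDDTHQH
IIc_ref1	IIc	WRKYGQKKMLPYSCMVGKCPDVVRSNDIFENMVDDLPLIRNHAH
IIc_ref2	IIc	WRKYGQKKMLPYSCMEGKCPDKVRSNDIFENMVDDFPLIRNHAH
IIc_ref3	IIc	WRKYGQKKMLPYSCMVGKCQDVVRSNGIFQNMVDDLPLIRNHAH
IId_ref1	IId	WRKYGQKKEGTAACRIQRCAGGAKVPKVFGNRKNRAYTSYTHSH
IId_ref2	IId	WRKYGQKKEGTVACRIQRCAGGAKVPKVMGNRKNRAYTGYTHSH
IId_ref3	IId	WRKYGQKKEGTKACRIQRCPGFAKVPKVFGNRKNRAYTSYTHSH
IIe_ref1	IIe	WRKYGQKYNGRSICNLNTCEFVNLNMILSDFGPRNALENLRHSH
IIe_ref2	IIe	WRKYGQKRNGRYICNLNTCVFVNLNMILSDFGPRNALENLRHSH
IIe_ref3	IIe	WRKYGQKYNGISICNLNTCEFVNLNTILSDVGPRNALENLRHSH
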