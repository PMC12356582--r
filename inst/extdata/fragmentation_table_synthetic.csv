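"name","formula","adduct","precursor_mz","fragment_mz","fragment_intensity","retention_time","citation"
"intermedine","C15H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;282.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"lycopsamine","C15H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;282.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"indicine","C15H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;282.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"echinatine","C15H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;282.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"rinderine","C15H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;282.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"intermedine N-oxide","C15H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;298.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"lycopsamine N-oxide","C15H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;298.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"indicine N-oxide","C15H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;298.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"echinatine N-oxide","C15H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;298.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"rinderine N-oxide","C15H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;298.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"heliotrine","C16H27NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;296.1856","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"heliotrine N-oxide","C16H27NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;312.1806","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"europine","C16H27NO6","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;312.1806","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"europine N-oxide","C16H27NO7","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;328.1755","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"echimidine","C20H31NO7","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;380.2068","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"echimidine N-oxide","C20H31NO8","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;396.2017","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"heliosupine","C20H31NO7","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;380.2068","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"heliosupine N-oxide","C20H31NO8","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;396.2017","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"lasiocarpine","C21H33NO7","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;394.2224","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"lasiocarpine N-oxide","C21H33NO8","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;410.2173","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"senecionine","C18H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;318.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"senecionine N-oxide","C18H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;334.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"integerrimine","C18H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;318.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"integerrimine N-oxide","C18H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;334.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"senecivernine","C18H25NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;318.1700","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"senecivernine N-oxide","C18H25NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;334.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"seneciphylline","C18H23NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;316.1543","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"seneciphylline N-oxide","C18H23NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;332.1492","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"spartioidine","C18H23NO5","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;316.1543","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"spartioidine N-oxide","C18H23NO6","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;332.1492","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"retrorsine","C18H25NO6","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;334.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"retrorsine N-oxide","C18H25NO7","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;350.1598","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"usaramine","C18H25NO6","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019;334.1649","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"usaramine N-oxide","C18H25NO7","[M+H]+",NA,"94.0651;120.0808;136.0757;138.0913;154.0863;172.0968;350.1598","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"senkirkine","C19H27NO6","[M+H]+",NA,"94.0651;120.0808;122.0964;138.0913;150.0913;168.1019;348.1806","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"platynecine","C8H15NO2","[M+H]+",NA,"94.0651;96.0808;120.0808;122.0964;138.0913;140.1070","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"retronecine","C8H13NO2","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019","",NA,"synthetic reconstruction from necine-class fragment chemistry"
"heliotridine","C8H13NO2","[M+H]+",NA,"94.0651;120.0808;138.0913;156.1019","",NA,"synthetic reconstruction from necine-class fragment chemistry"
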