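setting	scheme	base	accuracy	exact_match	hamming_loss	integrated_score
mashup_combined	rakel	svm_poly	0.818	0.754	0.042	0.591
mashup_combined	rakel	svm_rbf	0.757	0.670	0.055	0.479
mashup_combined	rakel	rf	0.803	0.743	0.045	0.570
mashup_combined	br	svm_poly	0.786	0.690	0.043	0.519
mashup_combined	br	svm_rbf	0.598	0.533	0.058	0.300
mashup_combined	br	rf	0.666	0.602	0.052	0.380
deepwalk	rakel	svm_poly	0.333	0.290	0.145	0.083
deepwalk	rakel	svm_rbf	0.342	0.304	0.140	0.089
deepwalk	rakel	rf	0.334	0.297	0.142	0.085
deepwalk	br	svm_poly	0.297	0.213	0.143	0.054
deepwalk	br	svm_rbf	0.059	0.057	0.118	0.003
deepwalk	br	rf	0.142	0.118	0.121	0.015
node2vec	rakel	svm_poly	0.774	0.698	0.050	0.513
node2vec	rakel	svm_rbf	0.738	0.668	0.059	0.464
node2vec	rakel	rf	0.762	0.695	0.054	0.501
node2vec	br	svm_poly	0.734	0.631	0.049	0.440
node2vec	br	svm_rbf	0.652	0.574	0.058	0.353
node2vec	br	rf	0.639	0.581	0.058	0.350
mashup_separated	rakel	svm_poly	0.814	0.749	0.043	0.583
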