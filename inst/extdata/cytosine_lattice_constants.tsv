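# lattice constants of anhydrous cytosine (C) and cytosine monohydrate (C-MH)
# determinations: reference = earlier single-crystal study, powder = Rietveld
# refinement of the powder pattern, dft = fully relaxed 0 K calculation
# units: lengths in angstrom, angles in degrees, volume in cubic angstrom
form	determination	a	b	c	alpha	beta	gamma	volume
C	reference	13.044	9.496	3.814	90	90	90	472.424
C	powder	13.044	9.507	3.820	90	90	90	473.68
C	dft	12.888	9.430	3.613	90	90	90	439.131
C-MH	reference	7.783	9.825	7.668	90	99.57	90	578.196
C-MH	powder	7.795	9.838	7.684	90	99.495	90	581.18
C-MH	dft	7.641	9.737	7.277	90	101.044	90	531.386
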