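GLU	map04724 glutamatergic synapse (illustrative subset)	Gria1	Gria2	Grin1	Grin2a	Grin2b	Grm1	Grm5	Slc1a2	Slc1a3	Slc17a6	Slc17a7	Gls	Glul	Dlg4	Shank2	Homer1
ACH	map04725 cholinergic synapse (illustrative subset)	Chat	Slc18a3	Slc5a7	Ache	Chrna4	Chrna7	Chrnb2	Chrm1	Chrm2	Chrm3	Kcnq2	Kcnq3	Cacna1a	Adcy1
5HT	map04726 serotonergic synapse (illustrative subset)	Tph2	Ddc	Slc6a4	Htr1a	Htr1b	Htr2a	Htr2c	Htr3a	Htr4	Htr7	Maoa	Maob	Gnai1	Kcnj3
GABA	map04727 GABAergic synapse (illustrative subset)	Gad1	Gad2	Slc32a1	Slc6a1	Gabra1	Gabra2	Gabrb1	Gabrb2	Gabrg2	Gabbr1	Gabbr2	Abat	Gphn	Src	Cacna1b
DA	map04728 dopaminergic synapse (illustrative subset)	Th	Ddc	Slc6a3	Slc18a2	Drd1	Drd2	Drd3	Drd4	Drd5	Comt	Ppp1r1b	Gsk3b	Akt1	Kif5a
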