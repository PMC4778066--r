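mirna_id	mirna_log2fc	target_id	target_rel
miR164	-2.38730699	orange1.1g030909m	1.4372
miR164	-2.38730699	orange1.1g047710m	0.6610
miR164	-2.38730699	orange1.1g017827m	2.9265
miR158	-6.05735341	orange1.1g001709m	4.1384
miR158	-6.05735341	orange1.1g002569m	3.2507
miR158	-6.05735341	orange1.1g038105m	1.6141
miR158	-6.05735341	orange1.1g041843m	0.7305
miR833	5.7705023	orange1.1g047519m	0.5503
miR1507	1.99337925	orange1.1g034576m	0.1031
miR1507	1.99337925	orange1.1g042037m	0.5256
miR1507	1.99337925	orange1.1g045522m	1.6070
miR156	-1.91583036	orange1.1g016971m	ND
miR156	-1.91583036	orange1.1g021420m	1.3295
miR156	-1.91583036	orange1.1g008680m	2.0745
miR156	-1.91583036	orange1.1g009653m	1.5065
miR156	-1.91583036	orange1.1g011640m	1.4202
miR156	-1.91583036	orange1.1g011651m	ND
miR156	-1.91583036	orange1.1g032310m	3.4314
miR156	-1.91583036	orange1.1g029650m	2.0105
miR156	-1.91583036	orange1.1g032937m	0.8213
miR156	-1.91583036	orange1.1g046416m	3.8189
miR156	-1.91583036	orange1.1g030599m	1.1053
miR7812	-7.07931495	orange1.1g017621m	0.7175
miR7812	-7.07931495	orange1.1g038769m	3.2200
miR5821	10.86451118	orange1.1g045278m	0.4220
miR5821	10.86451118	orange1.1g022991m	1.3523
miR5821	10.86451118	orange1.1g013216m	0.4598
miR5821	10.86451118	orange1.1g013368m	0.9147
miR5821	10.86451118	orange1.1g046783m	0.5710
miR395	10.30345436	orange1.1g005583m	0.9674
miR395	10.30345436	orange1.1g014749m	1.5667
miR395	10.30345436	AT3G22890	1.5017
miR395	10.30345436	AT4G14680	ND
miR395	10.30345436	AT5G43780	0.8727
miR395	10.30345436	AT5G1018	0.7439
miR1077	11.84568538	orange1.1g014749m	1.7085
miR946	10.29281625	orange1.1g005467m	0.4222
miR1160	5.35880943	orange1.1g005451m	0.8227
miR1160	5.35880943	orange1.1g004285m	1.1364
miR8019	6.3871206	orange1.1g010016m	2.5270
miR6218	3.83981303	orange1.1g005203m	0.7108
miR6218	3.83981303	orange1.1g003633m	0.8682
miR1533	4.30631516	orange1.1g007444m	0.6732
miR6426	4.30631516	orange1.1g037454m	0.8741
miR6426	4.30631516	orange1.1g010327m	0.8483
miR3946	-2.16322268	orange1.1g017665m	0.8570
miR3946	-2.16322268	orange1.1g013752m	9.9306
miR3946	-2.16322268	orange1.1g014958m	0.6579
miR3946	-2.16322268	orange1.1g005518m	1.2743
miR3946	-2.16322268	orange1.1g025914m	1.8616
miR3946	-2.16322268	orange1.1g024507m	1.1601
miR3946	-2.16322268	orange1.1g025497m	3.6019
miR3946	-2.16322268	orange1.1g011991m	6.0692
miR3946	-2.16322268	orange1.1g006091m	0.6423
miR3946	-2.16322268	orange1.1g009139m	1.4300
miR3946	-2.16322268	orange1.1g010449m	0.7370
miR3946	-2.16322268	orange1.1g002698m	2.1231
miR3946	-2.16322268	orange1.1g007773m	1.2461
miR3946	-2.16322268	orange1.1g002776m	ND
miR3946	-2.16322268	orange1.1g016142m	5.4132
miR3946	-2.16322268	orange1.1g030941m	0.7158
miR535	-1.56870368	orange1.1g009840m	1.8899
miR5256	-3.19897021	orange1.1g004233m	2.3193
miR5742	-2.88770785	orange1.1g009718m	1.9777
miR5742	-2.88770785	orange1.1g041155m	1.6675
miR5561	-7.70753451	orange1.1g018677m	2.5652
miR5561	-7.70753451	orange1.1g019071m	1.7283
miR5158	-5.92521928	orange1.1g043878m	1.9307
miR5158	-5.92521928	orange1.1g042649m	2.7431
miR5818	-4.95063483	orange1.1g001860m	3.9827
miR779	-8.10749886	orange1.1g027903m	3.9679
miR779	-8.10749886	orange1.1g044779m	7.1508
miR779	-8.10749886	orange1.1g041074m	7.9240
miR779	-8.10749886	orange1.1g042791m	2.2157
miR779	-8.10749886	orange1.1g001921m	9.5707
miR779	-8.10749886	orange1.1g025347m	21.0361
miR779	-8.10749886	orange1.1g045028m	0.7103
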