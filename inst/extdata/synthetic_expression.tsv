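sample	value
S01	10.4340194532207
S02	10.3031884476083
S03	10.551483416596
S04	11.2624762583309
S05	10.4074947721696
S06	11.4923960840633
S07	9.31884189903873
S08	10.2540001198648
S09	10.2946305430747
S10	12.5657031474599
S11	9.36609553362753
S12	9.58047535576501
S13	11.7171002396761
S14	10.3289693325962
S15	10.4080144172919
S16	10.2131141824109
S17	9.19488915366269
S18	9.80916275965957
S19	10.9409921891201
S20	9.48497012883287
S21	11.4946902598118
S22	10.5114408977587
S23	9.97678635757063
S24	10.8194597794726
S25	9.74734162895101
S26	11.0527887145995
S27	9.92408755259989
S28	9.40765936006107
S29	11.4596750855889
S30	9.56713007323671
S31	10.7939543110395
S32	9.94428030931249
S33	9.2739814859666
S34	11.3785639407384
S35	11.4026552020839
S36	11.1841313604852
S37	9.65381315983586
S38	11.167058678887
S39	10.5754350771816
S40	11.6064777158339
S41	11.0696374175533
S42	10.0509472779915
S43	9.41964264745535
S44	11.4898050630037
S45	10.4613682112213
S46	9.10922978987291
S47	9.89333679945568
S48	10.9547239500847
S49	11.4212690991646
S50	11.0712558829241
S51	11.4565008389893
S52	10.5396962797701
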