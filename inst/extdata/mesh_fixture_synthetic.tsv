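D006331	C14.280
D001919	C14.280.067
D054537	C14.280.123
D019559	C14.907.474
D011565	C17.800.859
D007249	C23.550.470
D020123	D02.065.589
D002220	D02.065.416
D064420	C25.100
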