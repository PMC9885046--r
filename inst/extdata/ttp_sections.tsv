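reaction_id	section
R02412	Input
R03460	Input
R01373	Shikimate
R01714	Shikimate
R01715	Shikimate
R02340	Tryptophan
R03508	Tryptophan
R03509	Tryptophan
R00674	Tryptophan
R01073	PheTyr
R02722	PheTyr
R00985	PheTyr
R00986	PheTyr
R03084	PheTyr
R02413	PheTyr
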