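drug	ld50_text	half_life_text	selected
Nefazodone	Cases of life-threatening hepatic failure have been reported in patients treated with nefazodone.	2–4 h	TRUE
Milnacipran	Oral LD50 rat: 213 mg/kg	6–8 h	TRUE
Mianserin	Oral LD50 rat: 780 mg/kg	10–17 h	TRUE
Trazodone	Oral LD50 rat: 690 mg/kg	7.3 +/− 0.8 h.	TRUE
Nortriptyline	Oral LD50 rat: 405 mg/kg	26 h	TRUE
Duloxetine	Fatalities have been reported with doses of 1000 mg involving both mixed drugs as well as duloxetine alone	12 h	TRUE
Clomipramine	One death involved a patient suspected of ingesting a dose of 7000 mg. The second death involved a patient suspected of ingesting a dose of 5750 mg.	32 h	TRUE
Reboxetine	Reports of seizures (rare) have been reported	12.5 h	FALSE
Mirtazapine	Oral LD50 rat: 830 mg/kg in male Swiss mice	20–40 h	FALSE
Venlafaxine	Overdose of venlafaxine is typically associated with mild symptoms	5 h	FALSE
Citalopram	Oral LD50 rat:179 mg/kg	35 h	FALSE
Fluoxetine	In a report that included 234 fluoxetine overdose cases, it was concluded that symptoms resulting from fluoxetine overdose were generally minor and short in duration	1–3 days	FALSE
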