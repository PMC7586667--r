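concept_id	english_name	synonym
insomnia	insomnia	不寐
agitation	agitation	烦躁
anxiety	anxiety	忧
erectile_dysfunction	erectile dysfunction	经隧失职
nausea	nausea	恶心
vomiting	vomiting	呕
vomiting	vomiting	吐
arrhythmia	arrhythmia	心悸
dizziness	dizziness	头昏
dizziness	dizziness	头眩
dry_mouth	dry mouth	口燥
hallucination	hallucination	妄见
tachycardia	tachycardia	心跳过速
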