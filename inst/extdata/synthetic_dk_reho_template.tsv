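region	d
bankssts	-0.237
caudalanteriorcingulate	-0.39
caudalmiddlefrontal	-0.301
cuneus	-0.384
entorhinal	-0.17
frontalpole	-0.415
fusiform	-0.27
inferiorparietal	-0.412
inferiortemporal	-0.342
insula	-0.36
isthmuscingulate	-0.276
lateraloccipital	-0.225
lateralorbitofrontal	-0.299
lingual	-0.269
medialorbitofrontal	-0.273
middletemporal	-0.296
paracentral	-0.104
parahippocampal	-0.229
parsopercularis	-0.266
parsorbitalis	-0.262
parstriangularis	-0.176
pericalcarine	-0.213
postcentral	-0.383
posteriorcingulate	-0.35
precentral	-0.33
precuneus	-0.226
rostralanteriorcingulate	-0.286
rostralmiddlefrontal	-0.288
superiorfrontal	-0.335
superiorparietal	-0.218
superiortemporal	-0.39
supramarginal	-0.396
temporalpole	-0.17
transversetemporal	-0.38
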