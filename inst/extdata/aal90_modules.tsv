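roi_code	full_name	module	hemisphere
PreCG.L	Precentral gyrus (left)	frontal	L
PreCG.R	Precentral gyrus (right)	frontal	R
SFGdor.L	Superior frontal gyrus, dorsolateral (left)	frontal	L
SFGdor.R	Superior frontal gyrus, dorsolateral (right)	frontal	R
ORBsup.L	Superior frontal gyrus, orbital part (left)	frontal	L
ORBsup.R	Superior frontal gyrus, orbital part (right)	frontal	R
MFG.L	Middle frontal gyrus (left)	frontal	L
MFG.R	Middle frontal gyrus (right)	frontal	R
ORBmid.L	Middle frontal gyrus, orbital part (left)	frontal	L
ORBmid.R	Middle frontal gyrus, orbital part (right)	frontal	R
IFGoperc.L	Inferior frontal gyrus, opercular part (left)	frontal	L
IFGoperc.R	Inferior frontal gyrus, opercular part (right)	frontal	R
IFGtriang.L	Inferior frontal gyrus, triangular part (left)	frontal	L
IFGtriang.R	Inferior frontal gyrus, triangular part (right)	frontal	R
ORBinf.L	Inferior frontal gyrus, orbital part (left)	frontal	L
ORBinf.R	Inferior frontal gyrus, orbital part (right)	frontal	R
ROL.L	Rolandic operculum (left)	frontal	L
ROL.R	Rolandic operculum (right)	frontal	R
SMA.L	Supplementary motor area (left)	frontal	L
SMA.R	Supplementary motor area (right)	frontal	R
OLF.L	Olfactory cortex (left)	frontal	L
OLF.R	Olfactory cortex (right)	frontal	R
SFGmed.L	Superior frontal gyrus, medial (left)	frontal	L
SFGmed.R	Superior frontal gyrus, medial (right)	frontal	R
ORBsupmed.L	Superior frontal gyrus, medial orbital (left)	frontal	L
ORBsupmed.R	Superior frontal gyrus, medial orbital (right)	frontal	R
REC.L	Gyrus rectus (left)	frontal	L
REC.R	Gyrus rectus (right)	frontal	R
INS.L	Insula (left)	subcortical	L
INS.R	Insula (right)	subcortical	R
ACG.L	Anterior cingulate and paracingulate gyri (left)	frontal	L
ACG.R	Anterior cingulate and paracingulate gyri (right)	frontal	R
DCG.L	Median cingulate and paracingulate gyri (left)	frontal	L
DCG.R	Median cingulate and paracingulate gyri (right)	frontal	R
PCG.L	Posterior cingulate gyrus (left)	parietal	L
PCG.R	Posterior cingulate gyrus (right)	parietal	R
HIP.L	Hippocampus (left)	subcortical	L
HIP.R	Hippocampus (right)	subcortical	R
PHG.L	Parahippocampal gyrus (left)	subcortical	L
PHG.R	Parahippocampal gyrus (right)	subcortical	R
AMYG.L	Amygdala (left)	subcortical	L
AMYG.R	Amygdala (right)	subcortical	R
CAL.L	Calcarine fissure and surrounding cortex (left)	occipital	L
CAL.R	Calcarine fissure and surrounding cortex (right)	occipital	R
CUN.L	Cuneus (left)	occipital	L
CUN.R	Cuneus (right)	occipital	R
LING.L	Lingual gyrus (left)	occipital	L
LING.R	Lingual gyrus (right)	occipital	R
SOG.L	Superior occipital gyrus (left)	occipital	L
SOG.R	Superior occipital gyrus (right)	occipital	R
MOG.L	Middle occipital gyrus (left)	occipital	L
MOG.R	Middle occipital gyrus (right)	occipital	R
IOG.L	Inferior occipital gyrus (left)	occipital	L
IOG.R	Inferior occipital gyrus (right)	occipital	R
FFG.L	Fusiform gyrus (left)	temporal	L
FFG.R	Fusiform gyrus (right)	temporal	R
PoCG.L	Postcentral gyrus (left)	parietal	L
PoCG.R	Postcentral gyrus (right)	parietal	R
SPG.L	Superior parietal gyrus (left)	parietal	L
SPG.R	Superior parietal gyrus (right)	parietal	R
IPL.L	Inferior parietal, supramarginal and angular gyri (left)	parietal	L
IPL.R	Inferior parietal, supramarginal and angular gyri (right)	parietal	R
SMG.L	Supramarginal gyrus (left)	parietal	L
SMG.R	Supramarginal gyrus (right)	parietal	R
ANG.L	Angular gyrus (left)	parietal	L
ANG.R	Angular gyrus (right)	parietal	R
PCUN.L	Precuneus (left)	parietal	L
PCUN.R	Precuneus (right)	parietal	R
PCL.L	Paracentral lobule (left)	parietal	L
PCL.R	Paracentral lobule (right)	parietal	R
CAU.L	Caudate nucleus (left)	subcortical	L
CAU.R	Caudate nucleus (right)	subcortical	R
PUT.L	Lenticular nucleus, putamen (left)	subcortical	L
PUT.R	Lenticular nucleus, putamen (right)	subcortical	R
PAL.L	Lenticular nucleus, pallidum (left)	subcortical	L
PAL.R	Lenticular nucleus, pallidum (right)	subcortical	R
THA.L	Thalamus (left)	subcortical	L
THA.R	Thalamus (right)	subcortical	R
HES.L	Heschl gyrus (left)	temporal	L
HES.R	Heschl gyrus (right)	temporal	R
STG.L	Superior temporal gyrus (left)	temporal	L
STG.R	Superior temporal gyrus (right)	temporal	R
TPOsup.L	Temporal pole: superior temporal gyrus (left)	temporal	L
TPOsup.R	Temporal pole: superior temporal gyrus (right)	temporal	R
MTG.L	Middle temporal gyrus (left)	temporal	L
MTG.R	Middle temporal gyrus (right)	temporal	R
TPOmid.L	Temporal pole: middle temporal gyrus (left)	temporal	L
TPOmid.R	Temporal pole: middle temporal gyrus (right)	temporal	R
ITG.L	Inferior temporal gyrus (left)	temporal	L
ITG.R	Inferior temporal gyrus (right)	temporal	R
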