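# Region -> lobe grouping of the Desikan-Killiany cortical parcels, following
# the FreeSurfer lobe assignment, kept to five lobes per hemisphere (the
# insula is folded into the frontal block; edit freely - this file is data,
# not code). Region labels are hemisphere-prefixed as <hemi>_<parcel>.
lh:
  frontal:
    - caudalmiddlefrontal
    - lateralorbitofrontal
    - medialorbitofrontal
    - paracentral
    - parsopercularis
    - parsorbitalis
    - parstriangularis
    - precentral
    - rostralmiddlefrontal
    - superiorfrontal
    - frontalpole
    - insula
  parietal:
    - inferiorparietal
    - postcentral
    - precuneus
    - superiorparietal
    - supramarginal
  temporal:
    - bankssts
    - entorhinal
    - fusiform
    - inferiortemporal
    - middletemporal
    - parahippocampal
    - superiortemporal
    - temporalpole
    - transversetemporal
  occipital:
    - cuneus
    - lateraloccipital
    - lingual
    - pericalcarine
  cingulate:
    - caudalanteriorcingulate
    - isthmuscingulate
    - posteriorcingulate
    - rostralanteriorcingulate
rh:
  frontal:
    - caudalmiddlefrontal
    - lateralorbitofrontal
    - medialorbitofrontal
    - paracentral
    - parsopercularis
    - parsorbitalis
    - parstriangularis
    - precentral
    - rostralmiddlefrontal
    - superiorfrontal
    - frontalpole
    - insula
  parietal:
    - inferiorparietal
    - postcentral
    - precuneus
    - superiorparietal
    - supramarginal
  temporal:
    - bankssts
    - entorhinal
    - fusiform
    - inferiortemporal
    - middletemporal
    - parahippocampal
    - superiortemporal
    - temporalpole
    - transversetemporal
  occipital:
    - cuneus
    - lateraloccipital
    - lingual
    - pericalcarine
  cingulate:
    - caudalanteriorcingulate
    - isthmuscingulate
    - posteriorcingulate
    - rostralanteriorcingulate
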