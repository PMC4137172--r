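raw_label	canonical
Cytoplasm	CYTOPLASM
Cytoplasmic	CYTOPLASM
Intracellular	CYTOPLASM
CytoplasmicMembrane	CYTOPLASMIC_MEMBRANE
Membrane	CYTOPLASMIC_MEMBRANE
Plasma membrane	CYTOPLASMIC_MEMBRANE
Lipid anchored	CYTOPLASMIC_MEMBRANE
Multi-transmembrane	CYTOPLASMIC_MEMBRANE
Cellwall	CELL_WALL
LPxTG cell wall anchored	CELL_WALL
Extracellular	EXTRACELLULAR
Secreted	EXTRACELLULAR
Secretory (released)	EXTRACELLULAR
Unknown	UNKNOWN
Unknown (may have multiple localization sites)	UNKNOWN
Non-cytoplasmic	SURFACE_UNKNOWN
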