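pattern	supercategory
plasma membrane	cell_surface
cell surface	cell_surface
extracellular matrix	cell_surface
extracellular region	cell_surface
extracellular space	cell_surface
cell periphery	cell_surface
anchored component of membrane	cell_surface
external side of plasma membrane	cell_surface
basement membrane	cell_surface
cytoskeleton	cytoskeleton
actin filament	cytoskeleton
actin cytoskeleton	cytoskeleton
microtubule	cytoskeleton
stress fiber	cytoskeleton
focal adhesion	cytoskeleton
intermediate filament	cytoskeleton
lamellipodium	cytoskeleton
filopodium	cytoskeleton
myosin complex	cytoskeleton
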