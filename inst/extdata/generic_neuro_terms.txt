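neuron
axon
brain
autis*
cns
nerve
glial
seizure
synap*
dendrit*
cortex
hippocamp*
cerebell*
neural
neuro*
glia
astrocyte
oligodendrocyte
spinal
cogniti*
memory
behavio*
epilep*
parkinson*
alzheimer*
psychiatr*
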