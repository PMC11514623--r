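# Two-latent brain/body trade-off model.
# Scaling indicators are listed first: intracranial volume (TIV) sets the
# unit of the brain latent, summed organ volumes set the unit of the
# lean-body latent. Height adjusts both latents and fat mass for body size.
# Divisors applied before estimation (variance balancing); the 10-vs-100
# assignment per variable is a package default.
#| rescale: TIV = 100, cerebrum = 100, cerebellum = 10, organs = 10, height = 10

brain =~ TIV + cerebrum + cerebellum
body  =~ organs + SM

brain ~ height
body  ~ brain + height
fat   ~ brain + height
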