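formulation,factor,source
base,1,active molecule; reference scale
hydrochloride,1.22,reported conversion rate (Leone et al. consensus)
bitartrate,1.89,reported conversion rate (Leone et al. consensus)
tartrate,2,reported conversion rate (Leone et al. consensus)
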