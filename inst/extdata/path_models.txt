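# Candidate causal models over migration distance, day length, extent of
# prealternate molt, foraging stratum, and extent of seasonal dichromatism.
# This set is a RECONSTRUCTION: the published analysis describes the shared
# constraints of its favored models (molt and stratum as direct parents of
# dichromatism; migration as a direct parent of day length; the two top
# models differing only in whether migration or day length parents molt;
# the runner-up proposing molt as conditionally independent) without
# enumerating all twelve graphs.  Each block is one sparse hypothesis of
# direct and indirect effects.  Edit freely; the file is data, not code.

id: m1
migration -> daylength
migration -> dichromatism
stratum -> dichromatism
vertices: migration daylength molt dichromatism stratum

id: m2
migration -> daylength
migration -> molt
molt -> dichromatism
stratum -> dichromatism

id: m3
migration -> daylength
daylength -> molt
molt -> dichromatism
stratum -> dichromatism

id: m4
migration -> daylength
daylength -> molt
molt -> dichromatism
vertices: migration daylength molt dichromatism stratum

id: m5
migration -> daylength
daylength -> dichromatism
stratum -> dichromatism
vertices: migration daylength molt dichromatism stratum

id: m6
migration -> daylength
migration -> molt
migration -> dichromatism
stratum -> dichromatism

id: m7
migration -> daylength
daylength -> molt
migration -> dichromatism
stratum -> dichromatism

id: m8
migration -> molt
molt -> dichromatism
stratum -> dichromatism
vertices: migration daylength molt dichromatism stratum

id: m9
migration -> daylength
daylength -> dichromatism
molt -> dichromatism
stratum -> dichromatism

id: m10
migration -> daylength
daylength -> molt
daylength -> dichromatism
stratum -> dichromatism

id: m11
migration -> daylength
migration -> molt
molt -> dichromatism
vertices: migration daylength molt dichromatism stratum

id: m12
migration -> daylength
stratum -> molt
molt -> dichromatism
stratum -> dichromatism
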