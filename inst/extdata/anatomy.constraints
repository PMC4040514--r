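# Model-checking constraints: for every binding of the IF patterns, the
# REQUIRE conjunction must have at least one satisfying instance in the
# saturated store.
#
# Every sinovial joint must have an articular capsule among its parts.
C1: IF (?j rdf:type mcf:Sinovial_joint) REQUIRE (?c rdf:type mcf:Articular_capsule) AND (?c mcf:PartOf ?j)
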