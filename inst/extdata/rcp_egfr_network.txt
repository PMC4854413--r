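# RCP/alpha5beta1/EGFR1 leading-edge signalling network, 41 nodes.
# One clamped input (EGF, sustained stimulation), two output GTPases
# (Rac1, RhoA), 38 intermediates. Basally active nodes (PDK1, mTor, c-Src,
# Pip2, Rac1) start ON; the input-less inhibitory phosphatases PTEN, SHIP2
# and PP2a are constitutive (clamped, default OFF).
# Rule provenance: "curated" = interaction named in the curation sources;
# "transcribed" = wiring read off the network diagram / pathway maps, exact
# gate not quotable.

[nodes]
EGF, input, 1
Rac1, output, 1
RhoA, output, 0
EGFR1, intermediate, 0
Shc, intermediate, 0
Grb2, intermediate, 0
Sos1, intermediate, 0
Ras, intermediate, 0
Raf1, intermediate, 0
MEK1/2, intermediate, 0
ERK1/2, intermediate, 0
p90RSK, intermediate, 0
Eps8, intermediate, 0
Abi1, intermediate, 0
Sos1E, intermediate, 0
Gab1, intermediate, 0
PI3K, intermediate, 0
Pip2, intermediate, 1
PIP3, intermediate, 0
PDK1, intermediate, 1
Akt, intermediate, 0
mTor, intermediate, 1
c-Src, intermediate, 1
IQGAP1, intermediate, 0
RacGAP1, intermediate, 0
pRacGAP1, intermediate, 0
Vav2, intermediate, 0
RalGDS, intermediate, 0
RalA, intermediate, 0
RalBP1, intermediate, 0
PLCgamma, intermediate, 0
DAG, intermediate, 0
IP3, intermediate, 0
Ca, intermediate, 0
PKC, intermediate, 0
Cdc42, intermediate, 0
Stat3, intermediate, 0
cCbl, intermediate, 0
PTEN, intermediate, 0, constitutive
SHIP2, intermediate, 0, constitutive
PP2a, intermediate, 0, constitutive

[rules]
EGFR1, EGF | curated: ligand engagement of the recycled receptor
Shc, EGFR1 | curated: receptor adaptor
Grb2, Shc | curated: Shc-Grb2 adaptor chain
Sos1, Grb2 AND NOT (ERK1/2 OR p90RSK) | curated: Grb2 recruitment; serine/threonine feedback phosphorylation by ERK1/2 or p90RSK dissociates and inactivates Sos1
Ras, Sos1 | curated: Sos1 exchange activity
Raf1, Ras | curated
MEK1/2, Raf1 | curated
ERK1/2, MEK1/2 | curated
p90RSK, ERK1/2 AND PDK1 | curated: ERK substrate, requires active PDK1 (AND gate)
Eps8, EGFR1 | curated: receptor substrate
Abi1, EGFR1 | transcribed: adaptor availability downstream of the receptor
Sos1E, Sos1 AND Eps8 AND Abi1 AND Ras | transcribed: tricomplex with Rac-specific GEF activity (AND gate); Ras conjunct for Ras-dependent complex activation
Gab1, Grb2 | curated: Grb2-bound scaffold
PI3K, EGFR1 OR Gab1 OR Ras | curated: receptor-, Gab1- and Ras-mediated recruitment
Pip2, Pip2 | transcribed: basal lipid pool, self-maintaining
PIP3, PI3K AND Pip2 AND NOT (PTEN OR SHIP2) | curated: PI3K product, reversed by the constitutive phosphatases
PDK1, PDK1 OR PIP3 | curated: basally active; PIP3-recruited
Akt, PIP3 AND PDK1 AND mTor AND NOT PP2a | curated: PIP3 recruitment with PDK1/mTORC2 phosphorylation (AND gate), opposed by PP2a
mTor, mTor OR Akt | transcribed: basally active; Akt-sustained
c-Src, c-Src OR EGFR1 | curated: basally active; receptor-enhanced
IQGAP1, c-Src | transcribed: scaffold engagement at the leading edge
RacGAP1, c-Src | transcribed: available pool at the front
pRacGAP1, Akt AND RacGAP1 AND IQGAP1 | curated: Akt phosphorylation with IQGAP1 recruitment (AND gate)
Vav2, PIP3 AND c-Src | curated: PIP3 binding and Src-family phosphorylation (AND gate)
RalGDS, Ras | curated: Ras effector
RalA, RalGDS | curated
RalBP1, RalA OR Ras | transcribed: Ral effector; redundant short Ras route as in the mined maps
PLCgamma, EGFR1 | curated
DAG, PLCgamma AND Pip2 | curated: lipid cleavage (AND gate)
IP3, PLCgamma AND Pip2 | curated: lipid cleavage (AND gate)
Ca, IP3 | curated
PKC, DAG AND Ca | curated: coincidence detector (AND gate)
Cdc42, Vav2 | curated: Vav2 exchange activity
Stat3, EGFR1 OR c-Src | curated
cCbl, EGFR1 | curated
Rac1, RalBP1 AND NOT (pRacGAP1 OR RhoA) OR Sos1E OR Vav2 AND NOT (pRacGAP1 OR RhoA) OR Rac1 AND NOT (pRacGAP1 OR RhoA) | compiled: precedence semantics for the declared hierarchy; RhoA antagonism guarded with the inhibitor
RhoA, Vav2 AND NOT Rac1 | curated: Vav2 exchange activity; mutual antagonism with Rac1

[hierarchy]
Sos1E > pRacGAP1 > RalBP1, Vav2
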