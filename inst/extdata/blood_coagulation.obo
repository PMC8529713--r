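format-version: 1.2

[Term]
id: GO:0007596
name: blood coagulation
def: "The sequential process in which the multiple coagulation factors of the blood interact, ultimately resulting in the formation of an insoluble fibrin clot; it may be divided into three stages: stage 1, the formation of intrinsic and extrinsic prothrombin converting principle; stage 2, the formation of thrombin; stage 3, the formation of stable fibrin polymers." [GOC:add]
synonym: "blood clotting" EXACT []
is_a: GO:0007599 ! hemostasis
is_a: GO:0050817 ! coagulation
relationship: part_of GO:0042060 ! wound healing

[Term]
id: GO:0007599
name: hemostasis
def: "The stopping of bleeding or the arrest of blood circulation to an organ or tissue." []

[Term]
id: GO:0050817
name: coagulation
def: "The process in which a fluid solution, or part of it, changes into a solid or semisolid mass." []

[Term]
id: GO:0042060
name: wound healing
def: "The series of events that restore integrity to damaged tissue following an injury." []
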