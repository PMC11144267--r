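# Structure-based alignment of the S6 pore span across channel subtypes
# (author residue numbering; one aligned position per row). version 1.0
trpv1,trpv3,trpv6
670,665,566
671,666,567
672,667,568
673,668,569
674,669,570
675,670,571
676,671,572
677,672,573
678,673,574
679,674,575
680,675,576
681,676,577
682,677,578
683,678,579
684,679,580
685,680,581
686,681,582
687,682,583
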