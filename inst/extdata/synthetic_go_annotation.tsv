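gene	term	term_name
SLC4A2	GO:S0001	transmembrane_transporter_activity
SLC6A1	GO:S0001	transmembrane_transporter_activity
SLC6A14	GO:S0001	transmembrane_transporter_activity
SLC9A7	GO:S0001	transmembrane_transporter_activity
SLC13A3	GO:S0001	transmembrane_transporter_activity
SLC13A4	GO:S0001	transmembrane_transporter_activity
SLC35D2	GO:S0001	transmembrane_transporter_activity
SLCO1A2	GO:S0001	transmembrane_transporter_activity
SLC39A10	GO:S0001	transmembrane_transporter_activity
SLC9B1	GO:S0001	transmembrane_transporter_activity
SLC22A25	GO:S0001	transmembrane_transporter_activity
SLC38A6	GO:S0001	transmembrane_transporter_activity
SPNS2	GO:S0001	transmembrane_transporter_activity
SLC4A2	GO:S0002	ion_transmembrane_transport
SLC9A7	GO:S0002	ion_transmembrane_transport
SLC9B1	GO:S0002	ion_transmembrane_transport
SLC13A3	GO:S0002	ion_transmembrane_transport
SLC13A4	GO:S0002	ion_transmembrane_transport
TRPM2	GO:S0002	ion_transmembrane_transport
TRPV1	GO:S0002	ion_transmembrane_transport
TRPC3	GO:S0002	ion_transmembrane_transport
PKD1	GO:S0002	ion_transmembrane_transport
SCN9A	GO:S0002	ion_transmembrane_transport
SLC6A1	GO:S0003	amino_acid_transmembrane_transport
SLC6A14	GO:S0003	amino_acid_transmembrane_transport
SLC38A6	GO:S0003	amino_acid_transmembrane_transport
CAT	GO:S0004	response_to_oxidative_stress
SOD2	GO:S0004	response_to_oxidative_stress
GSTM1	GO:S0004	response_to_oxidative_stress
GSTP1	GO:S0004	response_to_oxidative_stress
GSTT1	GO:S0004	response_to_oxidative_stress
NOS2	GO:S0004	response_to_oxidative_stress
NOS3	GO:S0004	response_to_oxidative_stress
PON1	GO:S0004	response_to_oxidative_stress
CYP2D6	GO:S0005	xenobiotic_metabolic_process
NAT2	GO:S0005	xenobiotic_metabolic_process
GSTM1	GO:S0005	xenobiotic_metabolic_process
GSTP1	GO:S0005	xenobiotic_metabolic_process
GSTT1	GO:S0005	xenobiotic_metabolic_process
TRPV5	GO:S0006	calcium_ion_transmembrane_transport
TRPV6	GO:S0006	calcium_ion_transmembrane_transport
TRPC1	GO:S0006	calcium_ion_transmembrane_transport
TRPM1	GO:S0006	calcium_ion_transmembrane_transport
PKD2	GO:S0006	calcium_ion_transmembrane_transport
MCOLN1	GO:S0006	calcium_ion_transmembrane_transport
SLC4A2	GO:S0007	regulation_of_intracellular_pH
SLC9A7	GO:S0007	regulation_of_intracellular_pH
SLC9B1	GO:S0007	regulation_of_intracellular_pH
SLCO1A2	GO:S0008	organic_anion_transport
SLC22A25	GO:S0008	organic_anion_transport
SLC13A3	GO:S0008	organic_anion_transport
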