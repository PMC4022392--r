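# WGS replicate metadata. replicate_id is sample/run-machine-slot; run,
# machine and slot derive from the replicate naming scheme (all WGS runs
# are high-throughput mode). The library column is a SYNTHETIC
# reconstruction consistent with the experiment design (inter-machine
# pairs share a preparation; intra-run/inter-run experiments include both
# same- and different-preparation pairs); it is not a published assignment.
replicate_id	sample	library	run	machine	mode	assay
NA12878/r1-1-1	NA12878	NA12878-wgs-L1	1	1	high-throughput	WGS
NA12878/r1-1-3	NA12878	NA12878-wgs-L2	1	1	high-throughput	WGS
NA12878/r2-1-1	NA12878	NA12878-wgs-L1	2	1	high-throughput	WGS
NA12878/r2-2-1	NA12878	NA12878-wgs-L1	2	2	high-throughput	WGS
NA12878/r3-1-1	NA12878	NA12878-wgs-L2	3	1	high-throughput	WGS
NA12878/r3-2-1	NA12878	NA12878-wgs-L2	3	2	high-throughput	WGS
NA12891/r3-1-2	NA12891	NA12891-wgs-L1	3	1	high-throughput	WGS
NA12892/r3-1-4	NA12892	NA12892-wgs-L1	3	1	high-throughput	WGS
NA18507/r2-1-3	NA18507	NA18507-wgs-L1	2	1	high-throughput	WGS
NA18507/r2-1-4	NA18507	NA18507-wgs-L2	2	1	high-throughput	WGS
NA18507/r3-1-3	NA18507	NA18507-wgs-L1	3	1	high-throughput	WGS
NA10080/r2-1-2	NA10080	NA10080-wgs-L1	2	1	high-throughput	WGS
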