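# WES replicate metadata. replicate_id is sample/run-machine-slot; run,
# machine, slot and mode derive from the replicate naming scheme (run 4 is
# the HiSeq 2500 rapid-run mode). The library column is a SYNTHETIC
# reconstruction consistent with the experiment design (inter-machine pairs
# share a preparation; intra-run/inter-run experiments include both same-
# and different-preparation pairs); it is not a published assignment.
replicate_id	sample	library	run	machine	mode	assay
NA12878/r1-1-1	NA12878	NA12878-wes-L1	1	1	high-throughput	WES
NA12878/r1-1-2	NA12878	NA12878-wes-L2	1	1	high-throughput	WES
NA12878/r2-1-1	NA12878	NA12878-wes-L1	2	1	high-throughput	WES
NA12878/r3-1-1	NA12878	NA12878-wes-L1	3	1	high-throughput	WES
NA12878/r3-2-1	NA12878	NA12878-wes-L1	3	2	high-throughput	WES
NA12878/r4-1-1	NA12878	NA12878-wes-L1	4	1	rapid	WES
NA12878/r4-2-1	NA12878	NA12878-wes-L1	4	2	rapid	WES
NA12891/r3-1-3	NA12891	NA12891-wes-L1	3	1	high-throughput	WES
NA12891/r4-1-3	NA12891	NA12891-wes-L1	4	1	rapid	WES
NA12891/r4-2-3	NA12891	NA12891-wes-L1	4	2	rapid	WES
NA12892/r3-1-4	NA12892	NA12892-wes-L1	3	1	high-throughput	WES
NA12892/r4-1-4	NA12892	NA12892-wes-L1	4	1	rapid	WES
NA12892/r4-2-4	NA12892	NA12892-wes-L1	4	2	rapid	WES
NA18507/r2-1-2	NA18507	NA18507-wes-L1	2	1	high-throughput	WES
NA18507/r2-1-3	NA18507	NA18507-wes-L2	2	1	high-throughput	WES
NA18507/r3-1-2	NA18507	NA18507-wes-L1	3	1	high-throughput	WES
NA18507/r4-1-2	NA18507	NA18507-wes-L1	4	1	rapid	WES
NA18507/r4-2-2	NA18507	NA18507-wes-L1	4	2	rapid	WES
NA10080/r2-1-4	NA10080	NA10080-wes-L1	2	1	high-throughput	WES
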