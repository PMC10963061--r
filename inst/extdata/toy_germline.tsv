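# tcrpair toy germline segment table (synthetic sequences, for tests/examples).
# V segments end at the conserved cysteine (inclusive); J segments start at the
# F/W anchor residue (inclusive). Segments are invented toy sequences, NOT real
# IMGT germline sequences.
# Schema: gene <TAB> segment
gene	segment
TRBV19	MSNQVLGGAEVSQTPSNKVTEKGKDVELRC
TRBV20-1	MLLGAVLLTQAWPGGLAALYLC
TRBJ1-1	FGQGTRLTVV
TRBJ2-1	FGPGTRLTVL
TRAV1-2	MKRILGALLGLLSAQVGSQGEEDPQALSIQEGENATMNC
TRAJ33	WGSGTKLIIKP
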