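[
  {"gene": "BRCA1",   "chrom": "chr17", "start": 41196312,  "end": 41277500},
  {"gene": "BRCA2",   "chrom": "chr13", "start": 32889611,  "end": 32973809},
  {"gene": "ATM",     "chrom": "chr11", "start": 108093559, "end": 108239826},
  {"gene": "BARD1",   "chrom": "chr2",  "start": 215590370, "end": 215674428},
  {"gene": "BRIP1",   "chrom": "chr17", "start": 59760656,  "end": 59940920},
  {"gene": "CDK12",   "chrom": "chr17", "start": 37617739,  "end": 37721160},
  {"gene": "CHEK1",   "chrom": "chr11", "start": 125495031, "end": 125525194},
  {"gene": "CHEK2",   "chrom": "chr22", "start": 29083731,  "end": 29137822},
  {"gene": "FANCL",   "chrom": "chr2",  "start": 58386377,  "end": 58468515},
  {"gene": "PALB2",   "chrom": "chr16", "start": 23614483,  "end": 23652631},
  {"gene": "PPP2R2A", "chrom": "chr8",  "start": 26149007,  "end": 26230196},
  {"gene": "RAD51B",  "chrom": "chr14", "start": 68286496,  "end": 69062279},
  {"gene": "RAD51C",  "chrom": "chr17", "start": 56769934,  "end": 56811703},
  {"gene": "RAD51D",  "chrom": "chr17", "start": 33426811,  "end": 33448541},
  {"gene": "RAD54L",  "chrom": "chr1",  "start": 46713304,  "end": 46744824},
  {"gene": "TP53",    "chrom": "chr17", "start": 7565097,   "end": 7590856},
  {"gene": "NF1",     "chrom": "chr17", "start": 29421944,  "end": 29709134},
  {"gene": "RB1",     "chrom": "chr13", "start": 48877882,  "end": 49056122},
  {"gene": "PIK3CA",  "chrom": "chr3",  "start": 178866310, "end": 178952497},
  {"gene": "CCNE1",   "chrom": "chr19", "start": 30302805,  "end": 30315215},
  {"gene": "PTEN",    "chrom": "chr10", "start": 89623194,  "end": 89728532},
  {"gene": "KRAS",    "chrom": "chr12", "start": 25358179,  "end": 25403870},
  {"gene": "NRAS",    "chrom": "chr1",  "start": 115247084, "end": 115259515},
  {"gene": "ARID1A",  "chrom": "chr1",  "start": 27022521,  "end": 27108601},
  {"gene": "MYC",     "chrom": "chr8",  "start": 128748314, "end": 128753680}
]
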