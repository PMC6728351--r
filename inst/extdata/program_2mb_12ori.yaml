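# Synthetic replication program: one 2 Mb chromosome, 12 origins with mixed
# firing times, fast-clock parameters (v_f 6 kb/min, sigma_t 2.6 min,
# l_coll 4.6 kb). Used by the analysis scripts and the acceptance runs.
chrom_lengths:
  chrS: 2000000
v_f: 6000.0
sigma_t: 2.6
s_t: 1.0
l_coll: 4600.0
l_init: 180.0
primer_len: 25.0
okazaki_len: 165.0
origins:
- chrom: chrS
  pos: 100000.0
  t_fire: 10.0
  label: ori01
- chrom: chrS
  pos: 260000.0
  t_fire: 22.0
  label: ori02
- chrom: chrS
  pos: 430000.0
  t_fire: 14.0
  label: ori03
- chrom: chrS
  pos: 610000.0
  t_fire: 30.0
  label: ori04
- chrom: chrS
  pos: 760000.0
  t_fire: 12.0
  label: ori05
- chrom: chrS
  pos: 930000.0
  t_fire: 25.0
  label: ori06
- chrom: chrS
  pos: 1100000.0
  t_fire: 16.0
  label: ori07
- chrom: chrS
  pos: 1290000.0
  t_fire: 28.0
  label: ori08
- chrom: chrS
  pos: 1450000.0
  t_fire: 10.0
  label: ori09
- chrom: chrS
  pos: 1620000.0
  t_fire: 24.0
  label: ori10
- chrom: chrS
  pos: 1780000.0
  t_fire: 14.0
  label: ori11
- chrom: chrS
  pos: 1930000.0
  t_fire: 26.0
  label: ori12
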