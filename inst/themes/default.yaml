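name: default
mode: default
classes:
  coordinate:
    fg: '#1F8B4C'
    bold: yes
  sample-info:
    fg: '#9BD0F0'
  read-name:
    fg: '#D7BA7D'
  flag:
    fg: '#E8854A'
  strand:
    fg: '#FF79C6'
    bold: yes
  record-type:
    fg: '#FFD75F'
    bold: yes
  meta-key:
    fg: '#56B6C2'
  meta-value:
    fg: '#9DA5B4'
  comment:
    fg: '#7F848E'
  unknown:
    fg: ~
  cigar.match:
    fg: '#3FB950'
  cigar.mismatch:
    fg: '#E3B341'
  cigar.insertion:
    fg: '#58A6FF'
  cigar.deletion:
    fg: '#F85149'
  cigar.skip:
    fg: '#BC8CFF'
  cigar.clip:
    fg: '#8B949E'
  cigar.pad:
    fg: '#6E7681'
  nucleotide.A:
    fg: '#00C896'
  nucleotide.C:
    fg: '#E62725'
  nucleotide.G:
    fg: '#FFB000'
  nucleotide.T:
    fg: '#335CFF'
  nucleotide.U:
    fg: '#4B70FF'
  nucleotide.R:
    fg: '#80BC4B'
  nucleotide.Y:
    fg: '#8C4292'
  nucleotide.S:
    fg: '#F26C12'
  nucleotide.W:
    fg: '#1A92CA'
  nucleotide.K:
    fg: '#736460'
  nucleotide.M:
    fg: '#565A46'
  nucleotide.B:
    fg: '#CD9C99'
  nucleotide.D:
    fg: '#9CBFB1'
  nucleotide.H:
    fg: '#96A1B9'
  nucleotide.V:
    fg: '#C2B382'
  nucleotide.N:
    fg: '#FFFFFF'
  aminoacid.A:
    fg: '#80A0F0'
  aminoacid.R:
    fg: '#F01505'
  aminoacid.N:
    fg: '#9DA5B4'
  aminoacid.D:
    fg: '#C048C0'
  aminoacid.C:
    fg: '#F08080'
  aminoacid.Q:
    fg: '#15C015'
  aminoacid.E:
    fg: '#C048C0'
  aminoacid.G:
    fg: '#F09048'
  aminoacid.H:
    fg: '#15A4A4'
  aminoacid.I:
    fg: '#80A0F0'
  aminoacid.L:
    fg: '#80A0F0'
  aminoacid.K:
    fg: '#F01505'
  aminoacid.M:
    fg: '#80A0F0'
  aminoacid.F:
    fg: '#80A0F0'
  aminoacid.P:
    fg: '#C0C000'
  aminoacid.S:
    fg: '#15C015'
  aminoacid.T:
    fg: '#15C015'
  aminoacid.W:
    fg: '#80A0F0'
  aminoacid.Y:
    fg: '#9DA5B4'
  aminoacid.V:
    fg: '#80A0F0'
  aminoacid.B:
    fg: '#9DA5B4'
  aminoacid.Z:
    fg: '#9DA5B4'
  aminoacid.X:
    fg: ~
  quality.0:
    fg: '#6E2B2B'
  quality.1:
    fg: '#A0522D'
  quality.2:
    fg: '#C8861E'
  quality.3:
    fg: '#D4C435'
  quality.4:
    fg: '#B8E06E'
  quality.5:
    fg: '#E8FFD0'
  feature.cds:
    fg: '#FFFFFF'
    bg: '#1F4E2C'
  feature.utr:
    fg: '#FFFFFF'
    bg: '#4E3A1F'
  feature.start-codon:
    fg: '#FFFFFF'
    bg: '#1F3A4E'
    bold: yes
  feature.stop-codon:
    fg: '#FFFFFF'
    bg: '#4E1F1F'
    bold: yes
  feature.other:
    fg: '#C9A26B'
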