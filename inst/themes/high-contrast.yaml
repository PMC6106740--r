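name: high-contrast
mode: high-contrast
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
    fg: '#4D5BD9'
  nucleotide.C:
    fg: '#AD9401'
  nucleotide.G:
    fg: '#DCBDB7'
  nucleotide.T:
    fg: '#07073D'
  nucleotide.U:
    fg: '#252554'
  nucleotide.R:
    fg: '#948CC8'
  nucleotide.Y:
    fg: '#5A4E1F'
  nucleotide.S:
    fg: '#C4A85C'
  nucleotide.W:
    fg: '#2A318B'
  nucleotide.K:
    fg: '#554A5C'
  nucleotide.M:
    fg: '#5E5A52'
  nucleotide.B:
    fg: '#B0A48E'
  nucleotide.D:
    fg: '#9B97BD'
  nucleotide.H:
    fg: '#918F96'
  nucleotide.V:
    fg: '#BFB6B0'
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
    fg: '#1A1A1A'
  quality.1:
    fg: '#4D4D4D'
  quality.2:
    fg: '#808080'
  quality.3:
    fg: '#ABABAB'
  quality.4:
    fg: '#D6D6D6'
  quality.5:
    fg: '#FFFFFF'
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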