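# Published amino-acid colour schemes, as reproduced by Jalview and
# ClustalX. Residues absent from a table (and gaps / X) render unstyled.
schemes:
  clustal:            # ClustalX default groups
    A: "#80A0F0"      # hydrophobic: blue
    I: "#80A0F0"
    L: "#80A0F0"
    M: "#80A0F0"
    F: "#80A0F0"
    W: "#80A0F0"
    V: "#80A0F0"
    C: "#F08080"      # cysteine: pink
    K: "#F01505"      # basic: red
    R: "#F01505"
    D: "#C048C0"      # acidic: magenta
    E: "#C048C0"
    N: "#15C015"      # polar: green
    Q: "#15C015"
    S: "#15C015"
    T: "#15C015"
    G: "#F09048"      # glycine: orange
    P: "#C0C000"      # proline: yellow
    H: "#15A4A4"      # aromatic polar: cyan
    Y: "#15A4A4"
  taylor:             # Taylor's physicochemical colour wheel
    A: "#CCFF00"
    R: "#0000FF"
    N: "#CC00FF"
    D: "#FF0000"
    C: "#FFFF00"
    Q: "#FF00CC"
    E: "#FF0066"
    G: "#FF9900"
    H: "#0066FF"
    I: "#66FF00"
    L: "#33FF00"
    K: "#6600FF"
    M: "#00FF00"
    F: "#00FF66"
    P: "#FFCC00"
    S: "#FF3300"
    T: "#FF6600"
    W: "#00CCFF"
    V: "#99FF00"
    Y: "#00FFCC"
  zappo:              # physicochemical groups
    I: "#FFAFAF"      # aliphatic/hydrophobic: rose
    L: "#FFAFAF"
    V: "#FFAFAF"
    A: "#FFAFAF"
    M: "#FFAFAF"
    F: "#FFC800"      # aromatic: orange
    W: "#FFC800"
    Y: "#FFC800"
    K: "#6464FF"      # positive: blue
    R: "#6464FF"
    H: "#6464FF"
    D: "#FF0000"      # negative: red
    E: "#FF0000"
    S: "#00FF00"      # hydrophilic: green
    T: "#00FF00"
    N: "#00FF00"
    Q: "#00FF00"
    P: "#FF00FF"      # conformationally special: magenta
    G: "#FF00FF"
    C: "#FFFF00"      # cysteine: yellow
  hydrophobicity:     # Kyte-Doolittle scale, red (hydrophobic) -> blue
    I: "#FF0000"
    V: "#F60009"
    L: "#EA0015"
    F: "#CB0034"
    C: "#C2003D"
    M: "#B0004F"
    A: "#AD0052"
    G: "#6A0095"
    T: "#61009E"
    S: "#5E00A1"
    W: "#5B00A4"
    Y: "#4F00B0"
    P: "#4600B9"
    H: "#1500EA"
    E: "#0C00F3"
    Q: "#0C00F3"
    D: "#0C00F3"
    N: "#0C00F3"
    B: "#0C00F3"
    Z: "#0C00F3"
    K: "#0000FF"
    R: "#0000FF"
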