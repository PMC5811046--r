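provenance: 'Constructed from published arrest-context experiments (strong: PPP, D/PP/D,
  PPW, APP, G/PP/G, PPN; weak: L/PP/L, CPP, HPP; X(-2) promoters H,K,Q,R,W; attenuators
  C,G,L,S,T), with the package''s default combination rule over effect classes.'
flank_effect:
  x_m2:
    A: MEDIUM_EFF
    C: WEAK_EFF
    D: MEDIUM_EFF
    E: MEDIUM_EFF
    F: MEDIUM_EFF
    G: WEAK_EFF
    H: STRONG_EFF
    I: MEDIUM_EFF
    K: STRONG_EFF
    L: WEAK_EFF
    M: MEDIUM_EFF
    'N': MEDIUM_EFF
    P: MEDIUM_EFF
    Q: STRONG_EFF
    R: STRONG_EFF
    S: WEAK_EFF
    T: WEAK_EFF
    V: MEDIUM_EFF
    W: STRONG_EFF
    'Y': MEDIUM_EFF
  x_m1:
    A: STRONG_EFF
    C: WEAK_EFF
    D: STRONG_EFF
    E: MEDIUM_EFF
    F: MEDIUM_EFF
    G: STRONG_EFF
    H: WEAK_EFF
    I: MEDIUM_EFF
    K: MEDIUM_EFF
    L: WEAK_EFF
    M: MEDIUM_EFF
    'N': MEDIUM_EFF
    P: STRONG_EFF
    Q: MEDIUM_EFF
    R: MEDIUM_EFF
    S: MEDIUM_EFF
    T: MEDIUM_EFF
    V: MEDIUM_EFF
    W: MEDIUM_EFF
    'Y': MEDIUM_EFF
  x_p1:
    A: MEDIUM_EFF
    C: MEDIUM_EFF
    D: STRONG_EFF
    E: MEDIUM_EFF
    F: MEDIUM_EFF
    G: STRONG_EFF
    H: MEDIUM_EFF
    I: MEDIUM_EFF
    K: MEDIUM_EFF
    L: WEAK_EFF
    M: MEDIUM_EFF
    'N': STRONG_EFF
    P: STRONG_EFF
    Q: MEDIUM_EFF
    R: MEDIUM_EFF
    S: MEDIUM_EFF
    T: MEDIUM_EFF
    V: MEDIUM_EFF
    W: STRONG_EFF
    'Y': MEDIUM_EFF
combination_rules:
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: WEAK
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: WEAK
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: WEAK
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: WEAK_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: WEAK
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: WEAK
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: MEDIUM_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: WEAK_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: MEDIUM_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: MEDIUM
- n_cat: 3+
  e_m2: WEAK_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: MEDIUM_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: '2'
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: STRONG
- n_cat: 3+
  e_m2: STRONG_EFF
  e_m1: STRONG_EFF
  e_p1: STRONG_EFF
  strength: STRONG
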