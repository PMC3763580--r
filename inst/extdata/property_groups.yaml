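# Three-group partitions of the 20-letter amino-acid alphabet for eight
# physicochemical properties. Property order and group order are fixed:
# feature indices are derived from this file, so reordering entries
# changes column meanings. Each property's three groups must be disjoint
# and cover the full alphabet ACDEFGHIKLMNPQRSTVWY.
#
# Users with their own division scheme can copy this file, edit the
# memberships, and pass it to read_property_groups().
properties:
  - name: secondary_structure
    code: ss
    groups:
      helix: EALMQKRH
      strand: VIYCWFT
      coil: GNPSD
  - name: solvent_accessibility
    code: sa
    groups:
      buried: ALFCGIVW
      exposed: RKQEND
      intermediate: MPSTHY
  - name: vdw_volume
    code: vdw
    groups:
      small: GASTPDC
      medium: NVEQIL
      large: MHKFRYW
  - name: hydrophobicity
    code: hyd
    groups:
      polar: RKEDQN
      neutral: GASTPHY
      hydrophobic: CLVIMFW
  - name: charge
    code: chg
    groups:
      positive: KR
      neutral: ANCQGHILMFPSTWYV
      negative: DE
  - name: polarizability
    code: plz
    groups:
      low: GASDT
      medium: CPNVEQIL
      high: KMHFRYW
  - name: polarity
    code: pol
    groups:
      low: LIFWCMVY
      medium: PATGS
      high: HQRKNED
  - name: surface_tension
    code: st
    groups:
      low: GQDNAHR
      medium: KTSEC
      high: ILMFPWYV
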