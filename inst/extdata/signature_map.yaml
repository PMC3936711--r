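# Signature-gene map for CRISPR-Cas type/subtype assignment.
# role: type_signature   -- presence calls the type even with no subtype
#       subtype_signature -- presence calls the subtype (and its parent type)
#       generic          -- known cas family carrying no type information
# requires: signature only counts when the named family is also in the locus
#           (cas4 occurs in type I systems too; alone it is not II evidence).
# Subtype II-C carries no signature family: it is called by exact composition
# {cas9, cas1, cas2}, and only for loci on complete genomes.
types: [I, II, III]
subtypes: [I-A, I-B, I-C, IC-variant, I-D, I-E, I-F, II-A, II-B, II-C, III-A, III-B]
families:
  cas3:     {type: I,   subtype: ~,          role: type_signature}
  cas9:     {type: II,  subtype: ~,          role: type_signature}
  cas10:    {type: III, subtype: ~,          role: type_signature}
  cas8a1:   {type: I,   subtype: I-A,        role: subtype_signature}
  cas8b:    {type: I,   subtype: I-B,        role: subtype_signature}
  cas8c:    {type: I,   subtype: I-C,        role: subtype_signature}
  GSU0054:  {type: I,   subtype: IC-variant, role: subtype_signature}
  GSU0053:  {type: I,   subtype: IC-variant, role: subtype_signature}
  cas10d:   {type: I,   subtype: I-D,        role: subtype_signature}
  cse1:     {type: I,   subtype: I-E,        role: subtype_signature}
  csy1:     {type: I,   subtype: I-F,        role: subtype_signature}
  csn2:     {type: II,  subtype: II-A,       role: subtype_signature}
  cas4:     {type: II,  subtype: II-B,       role: subtype_signature, requires: cas9}
  csm2:     {type: III, subtype: III-A,      role: subtype_signature}
  cmr:      {type: III, subtype: III-B,      role: subtype_signature}
  cas1:     {type: ~, subtype: ~, role: generic}
  cas2:     {type: ~, subtype: ~, role: generic}
  cas5:     {type: ~, subtype: ~, role: generic}
  cas6:     {type: ~, subtype: ~, role: generic}
  cas7:     {type: ~, subtype: ~, role: generic}
  RAMP:     {type: ~, subtype: ~, role: generic}
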