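experiment:
  id: exp1
  label: Colocalization test
  hypothesis: H1
  goals:
  - measure colocalization
  created_at: 2021-05-04T10:00:00
plans:
- id: prot1
  subtype: Protocol
- id: meth1
  subtype: Method
  parent_plan: prot1
steps:
- id: s1
  label: Preparation
  subtype: NonComputational
  inputs:
  - mat1
  - d1
- id: s2
  label: Transfection
  subtype: NonComputational
  preceded_by: s1
  inputs:
  - mat1
  method_used: meth1
- id: s3
  label: Image Acquisition
  subtype: Computational
  plan: prot1
  preceded_by: s2
  outputs:
  - d2
agents:
- id: a1
  name: Alice
  role: Experimenter
  orcid: 0000-0001-2345-678X
activities:
- id: act1
  start: 2021-05-04T10:00:00
  end: 2021-05-04T11:00:00
  used:
  - d1
  generated:
  - d2
  execution_order: 1.0
instruments:
- id: mic1
  label: LSM 880
  subtype: Microscope
  settings:
  - set1
- id: obj1
  label: 63x
  subtype: Objective
  part_of: mic1
  settings:
  - set2
materials:
- id: mat1
  label: pCherry-RAD54
  subtype: Plasmid
settings:
- id: set1
  subtype: InstrumentSettings
  key: laser power
  value: '0.5'
- id: set2
  subtype: InstrumentSettings
  key: zoom
  value: '1.0'
data:
- id: d1
  label: protocol paper
  category: Publication
  doi: 10.1000/xyz
- id: d2
  label: image
  category: RawData
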