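{
  "name": "MRCA", "variants": [], "children": [
    {"name": "M", "variants": ["16223"], "coding": ["10400"], "children": [
      {"name": "D", "variants": [], "coding": ["5178"], "children": [
        {"name": "D4", "variants": ["16362"], "coding": ["3010"], "children": [
          {"name": "D4j3", "variants": ["16286"], "children": []}
        ]},
        {"name": "D5", "variants": ["16189"], "coding": ["1107"], "children": [
          {"name": "D5a2a", "variants": ["16172"], "children": []}
        ]}
      ]},
      {"name": "G", "variants": ["16362"], "coding": ["4833"], "children": [
        {"name": "G2a", "variants": ["16278"], "coding": ["7600"], "children": []},
        {"name": "G2b1b", "variants": ["16130"], "children": []},
        {"name": "G3", "variants": ["16274"], "children": [
          {"name": "G3a1", "variants": ["16215"], "children": []}
        ]}
      ]},
      {"name": "M8", "variants": ["16298"], "children": [
        {"name": "C", "variants": ["16327"], "coding": ["3552"], "children": [
          {"name": "C4d", "variants": ["16093"], "children": []},
          {"name": "C4a2'3'4", "variants": ["16357"], "children": []}
        ]},
        {"name": "Z", "variants": ["16185", "16260"], "children": []}
      ]},
      {"name": "M7", "variants": [], "coding": ["6455"], "children": [
        {"name": "M7b", "variants": ["16129", "16192"], "children": []}
      ]},
      {"name": "M9", "variants": ["16234"], "coding": ["3394"], "children": [
        {"name": "M9a", "variants": ["16316"], "children": [
          {"name": "M9a1a", "variants": ["16092"], "children": []},
          {"name": "M9a1b1", "variants": ["16145"], "children": []}
        ]},
        {"name": "M9b", "variants": ["16167"], "children": []}
      ]},
      {"name": "M10", "variants": ["16311"], "children": []},
      {"name": "M13a1b", "variants": ["16148", "16381"], "children": []},
      {"name": "M62b", "variants": ["16305"], "children": []},
      {"name": "M74a", "variants": ["16140"], "children": []},
      {"name": "M33c", "variants": ["16169"], "children": []}
    ]},
    {"name": "N", "variants": [], "coding": ["10873"], "children": [
      {"name": "A", "variants": ["16290", "16319"], "coding": ["663"], "children": [
        {"name": "A4", "variants": ["16242"], "children": []},
        {"name": "A11", "variants": ["16248"], "children": [
          {"name": "A11b", "variants": ["16249"], "children": []}
        ]}
      ]},
      {"name": "N9a", "variants": ["16257A", "16261"], "children": []},
      {"name": "R", "variants": [], "coding": ["12705"], "children": [
        {"name": "B4", "variants": ["16217"], "children": []},
        {"name": "B5b", "variants": ["16243"], "children": []},
        {"name": "F1", "variants": ["16304"], "coding": ["6392"], "children": [
          {"name": "F1a", "variants": ["16162"], "children": []}
        ]},
        {"name": "U", "variants": [], "coding": ["12308"], "children": []}
      ]}
    ]}
  ]
}
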