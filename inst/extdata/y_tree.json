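{
  "name": "Y", "variants": [], "children": [
    {"name": "CT", "variants": ["M168"], "children": [
      {"name": "DE", "variants": ["M1"], "children": [
        {"name": "D", "variants": ["M174"], "children": [
          {"name": "D1", "variants": ["M15"], "children": []},
          {"name": "D3a", "variants": ["P47"], "children": []}
        ]}
      ]},
      {"name": "CF", "variants": ["P143"], "children": [
        {"name": "C", "variants": ["M130"], "children": [
          {"name": "C1", "variants": ["M105"], "children": []},
          {"name": "C2", "variants": ["M38"], "children": []},
          {"name": "C3", "variants": ["M217"], "children": []},
          {"name": "C5", "variants": ["M356"], "children": []},
          {"name": "C6", "variants": ["M347"], "children": []}
        ]},
        {"name": "F", "variants": ["M89"], "children": [
          {"name": "G", "variants": ["M201"], "children": []},
          {"name": "J", "variants": ["M304"], "children": []},
          {"name": "K", "variants": ["M9"], "children": [
            {"name": "NO", "variants": ["M214"], "children": [
              {"name": "N", "variants": ["M231"], "children": [
                {"name": "N1c1a", "variants": ["M178"], "children": []}
              ]},
              {"name": "O", "variants": ["M175"], "children": [
                {"name": "O1", "variants": ["M119"], "children": [
                  {"name": "O1a1", "variants": ["P203"], "children": []}
                ]},
                {"name": "O2", "variants": ["M268"], "children": [
                  {"name": "O2a1", "variants": ["M95"], "children": []}
                ]},
                {"name": "O3", "variants": ["M122"], "children": [
                  {"name": "O3a1c", "variants": ["002611"], "children": []},
                  {"name": "O3a2", "variants": ["P201"], "children": [
                    {"name": "O3a2b", "variants": ["M7"], "children": []},
                    {"name": "O3a2c1", "variants": ["M134"], "children": [
                      {"name": "O3a2c1a", "variants": ["M117"], "children": []}
                    ]}
                  ]}
                ]}
              ]}
            ]},
            {"name": "P", "variants": ["M45"], "children": [
              {"name": "Q", "variants": ["M242"], "children": [
                {"name": "Q1a1", "variants": ["M120"], "children": []}
              ]},
              {"name": "R", "variants": ["M207"], "children": [
                {"name": "R2", "variants": ["M124"], "children": []}
              ]}
            ]}
          ]}
        ]}
      ]}
    ]}
  ]
}
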