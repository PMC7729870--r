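{
  "label": "mt-MRCA",
  "variants": [],
  "children": [
    {
      "label": "L1",
      "variants": ["A769G", "A1018G"],
      "children": [
        {"label": "L1c", "variants": ["C3796T", "G5951A"], "children": []}
      ]
    },
    {
      "label": "N",
      "variants": ["G8701A", "C9540T"],
      "children": [
        {
          "label": "R",
          "variants": ["T12705C"],
          "children": [
            {
              "label": "HV",
              "variants": ["T14766C", "C2259T"],
              "children": [
                {
                  "label": "H",
                  "variants": ["G2706A", "T7028C"],
                  "children": [
                    {"label": "H1", "variants": ["G3010A", "A4745G"], "children": []}
                  ]
                }
              ]
            },
            {
              "label": "B",
              "variants": ["T16189C", "G499A"],
              "children": []
            }
          ]
        }
      ]
    }
  ]
}
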