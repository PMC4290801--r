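[
  {
    "label": "Any_1",
    "children": [
      {
        "label": "AA CC",
        "children": null
      },
      {
        "label": "AG CC",
        "children": null
      },
      {
        "label": "AG CT",
        "children": null
      },
      {
        "label": "GG CT",
        "children": null
      }
    ]
  },
  {
    "label": "Any_2",
    "children": [
      {
        "label": "CC GG",
        "children": null
      },
      {
        "label": "CT AG",
        "children": [
          {
            "label": "CT AG",
            "children": null
          },
          {
            "label": "CT GG",
            "children": null
          },
          {
            "label": "TT AG",
            "children": null
          }
        ]
      }
    ]
  },
  {
    "label": "Any_3",
    "children": [
      {
        "label": "CC AG",
        "children": null
      },
      {
        "label": "CC GG",
        "children": null
      },
      {
        "label": "CT AG",
        "children": null
      },
      {
        "label": "CT GG",
        "children": null
      },
      {
        "label": "TT GG",
        "children": null
      }
    ]
  },
  {
    "label": "Any_4",
    "children": [
      {
        "label": "AA CC",
        "children": null
      },
      {
        "label": "AG CT",
        "children": null
      }
    ]
  }
]
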