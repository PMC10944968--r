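{
  "nodes": ["EVC_contra", "EVC_ipsi", "IPS_contra", "IPS_ipsi", "MFG_contra", "MFG_ipsi", "SFG"],
  "rank": [1, 1, 2, 2, 4, 4, 3],
  "edges": [
    {
      "from": "EVC_contra",
      "to": "IPS_contra",
      "type": "feedforward"
    },
    {
      "from": "EVC_contra",
      "to": "SFG",
      "type": "feedforward"
    },
    {
      "from": "EVC_contra",
      "to": "MFG_contra",
      "type": "feedforward"
    },
    {
      "from": "IPS_contra",
      "to": "SFG",
      "type": "feedforward"
    },
    {
      "from": "IPS_contra",
      "to": "MFG_contra",
      "type": "feedforward"
    },
    {
      "from": "SFG",
      "to": "MFG_contra",
      "type": "feedforward"
    },
    {
      "from": "EVC_ipsi",
      "to": "IPS_ipsi",
      "type": "feedforward"
    },
    {
      "from": "EVC_ipsi",
      "to": "SFG",
      "type": "feedforward"
    },
    {
      "from": "EVC_ipsi",
      "to": "MFG_ipsi",
      "type": "feedforward"
    },
    {
      "from": "IPS_ipsi",
      "to": "SFG",
      "type": "feedforward"
    },
    {
      "from": "IPS_ipsi",
      "to": "MFG_ipsi",
      "type": "feedforward"
    },
    {
      "from": "SFG",
      "to": "MFG_ipsi",
      "type": "feedforward"
    },
    {
      "from": "IPS_contra",
      "to": "EVC_contra",
      "type": "feedback"
    },
    {
      "from": "SFG",
      "to": "EVC_contra",
      "type": "feedback"
    },
    {
      "from": "MFG_contra",
      "to": "EVC_contra",
      "type": "feedback"
    },
    {
      "from": "SFG",
      "to": "IPS_contra",
      "type": "feedback"
    },
    {
      "from": "MFG_contra",
      "to": "IPS_contra",
      "type": "feedback"
    },
    {
      "from": "MFG_contra",
      "to": "SFG",
      "type": "feedback"
    },
    {
      "from": "IPS_ipsi",
      "to": "EVC_ipsi",
      "type": "feedback"
    },
    {
      "from": "SFG",
      "to": "EVC_ipsi",
      "type": "feedback"
    },
    {
      "from": "MFG_ipsi",
      "to": "EVC_ipsi",
      "type": "feedback"
    },
    {
      "from": "SFG",
      "to": "IPS_ipsi",
      "type": "feedback"
    },
    {
      "from": "MFG_ipsi",
      "to": "IPS_ipsi",
      "type": "feedback"
    },
    {
      "from": "MFG_ipsi",
      "to": "SFG",
      "type": "feedback"
    },
    {
      "from": "EVC_contra",
      "to": "EVC_ipsi",
      "type": "lateral"
    },
    {
      "from": "EVC_ipsi",
      "to": "EVC_contra",
      "type": "lateral"
    },
    {
      "from": "IPS_contra",
      "to": "IPS_ipsi",
      "type": "lateral"
    },
    {
      "from": "IPS_ipsi",
      "to": "IPS_contra",
      "type": "lateral"
    },
    {
      "from": "MFG_contra",
      "to": "MFG_ipsi",
      "type": "lateral"
    },
    {
      "from": "MFG_ipsi",
      "to": "MFG_contra",
      "type": "lateral"
    }
  ],
  "b_mask": [true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true, true]
}
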