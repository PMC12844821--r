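multipack_patterns:
- combo
- variety pack
- multipack
- assorted
categories:
  Milk, milk product or milk substitute:
    dimensions:
    - name: animal_of_origin
      tier: primary
      values:
      - value: cow
        patterns:
        - cow
        - αγελαδ
      - value: sheep
        patterns:
        - sheep
        - προβει
      - value: goat
        patterns:
        - goat
        - κατσικ
        - γιδ
      - value: mixed milk
        patterns: mixed
      - value: almond
        patterns: almond
      - value: oat
        patterns: \boat\b
      NA: ~
    - name: processing
      tier: primary
      values:
      - value: pasteurized
        patterns:
        - pasteurized
        - pasteurised
        - fresh
      - value: UHT
        patterns:
        - uht
        - long life
      - value: condensed
        patterns: condensed
      - value: powder
        patterns: powder
      - value: strained
        patterns:
        - strained
        - στραγγιστ
      - value: fermented
        patterns:
        - fermented
        - kefir
      NA: ~
    - name: fat_content
      tier: primary
      values:
      - value: 2% fat
        patterns:
        - semi skimmed
        - 2% fat
        - 1 5% fat
        - light
      - value: 0% fat
        patterns:
        - 0% fat
        - skimmed
        - fat free
        - 0%
      - value: full fat
        patterns:
        - full fat
        - whole
      NA: ~
    - name: flavor
      tier: primary
      values:
      - value: chocolate
        patterns:
        - chocolate
        - cocoa
        - σοκολατ
      - value: strawberry
        patterns:
        - strawberry
        - φραουλ
      - value: vanilla
        patterns:
        - vanilla
        - βανιλια
      - value: plain
        patterns:
        - plain
        - πλαιν
      NA: ~
    - name: sweetener
      tier: secondary
      values:
      - value: with sweeteners
        patterns:
        - sweetener
        - stevia
        - steviol
        - aspartame
        - sucralose
      - value: with honey
        patterns: honey
      - value: with sugar
        patterns:
        - \bsugar\b
        - sucrose
        - glucose syrup
      NA: ~
    - name: protein_fortification
      tier: secondary
      values:
      - value: protein fortified
        patterns:
        - whey protein
        - pea protein
        - milk protein
        - added protein
      NA: ~
  Fat or fat product:
    dimensions:
    - name: source
      tier: primary
      values:
      - value: cow
        patterns: cow
      - value: sunflower and olive oil mix
        patterns:
        - sunflower and olive
        - oil mix
      - value: sunflower
        patterns: sunflower
      - value: olive
        patterns: olive
      NA: ~
    - name: form
      tier: primary
      values:
      - value: spreadable
        patterns:
        - spreadable
        - spread
      - value: solid
        patterns:
        - solid
        - block
      - value: liquid
        patterns: liquid
      NA: ~
    - name: salting
      tier: primary
      values:
      - value: unsalted
        patterns: unsalted
      - value: salted
        patterns: (?<!un)salted
      NA: ~
    - name: bioactives
      tier: secondary
      values:
      - value: with plant sterols
        patterns:
        - plant sterol
        - sterols
        - stanols
      - value: with yogurt
        patterns: yogurt
      NA: ~
  Grain or grain product:
    dimensions:
    - name: main_grain
      tier: primary
      values:
      - value: multigrain
        patterns:
        - multigrain
        - multi grain
      - value: wheat
        patterns: wheat
      - value: oat
        patterns: \boat
      - value: rye
        patterns: rye
      - value: spelt
        patterns: spelt
      - value: corn
        patterns:
        - \bcorn\b
        - maize
      NA: ~
    - name: processing
      tier: primary
      values:
      - value: wholegrain
        patterns:
        - wholegrain
        - whole grain
        - wholemeal
      - value: white
        patterns: white
      - value: dried
        patterns: dried
      - value: baked
        patterns: baked
      NA: ~
    - name: form
      tier: primary
      values:
      - value: sliced
        patterns: sliced
      - value: loaf
        patterns: loaf
      - value: rusks
        patterns:
        - rusk
        - παξιμαδ
      NA: ~
    - name: coating_or_filling
      tier: primary
      values:
      - value: chocolate coating
        patterns:
        - chocolate coating
        - chocolate coated
      - value: fruit filling
        patterns:
        - fruit filling
        - fruit filled
      - value: plain
        patterns: plain
      NA: ~
    - name: sweetener
      tier: secondary
      values:
      - value: with sweeteners
        patterns:
        - sweetener
        - stevia
        - steviol
        - aspartame
        - sucralose
      - value: with honey
        patterns: honey
      - value: with sugar
        patterns:
        - \bsugar\b
        - sucrose
        - glucose syrup
      NA: ~
    - name: fiber_fortification
      tier: secondary
      values:
      - value: fiber fortified
        patterns:
        - glucomannan
        - added fiber
        - fibre fortified
        - inulin
      NA: ~
  Vegetable or vegetable product:
    dimensions:
    - name: processing
      tier: primary
      values:
      - value: canned
        patterns:
        - canned
        - tinned
      - value: frozen
        patterns: frozen
      - value: dried
        patterns: dried
      - value: roasted
        patterns: roasted
      NA: ~
    - name: liquid_matrix
      tier: primary
      values:
      - value: in brine
        patterns: brine
      - value: in oil
        patterns: in oil
      - value: in syrup
        patterns: syrup
      - value: in water
        patterns: in water
      NA: ~
    - name: seasoning
      tier: primary
      values:
      - value: with spices
        patterns:
        - with spices
        - spiced
      NA: ~
    - name: consumption
      tier: secondary
      values:
      - value: strained
        patterns:
        - strained
        - drained
        - consume without liquid
      - value: non-strained
        patterns:
        - non strained
        - with liquid
      NA: ~
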