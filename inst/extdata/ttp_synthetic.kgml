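<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic reconstruction of an aromatic amino acid biosynthesis pathway
     map for parser testing: the 15 reaction ids are the cross-organism
     common core of the pathway; the wiring is a plausible chain-and-branch
     topology with synthetic compound ids, not a KEGG download. -->
<pathway name="path:syn00400" org="syn" number="00400"
         title="Synthetic aromatic amino acid biosynthesis">
  <reaction id="1" name="rn:R02412" type="irreversible">
    <substrate id="101" name="cpd:C90001"/>
    <product id="102" name="cpd:C90002"/>
  </reaction>
  <reaction id="2" name="rn:R03460" type="irreversible">
    <substrate id="102" name="cpd:C90002"/>
    <product id="103" name="cpd:C90003"/>
  </reaction>
  <reaction id="3" name="rn:R01373" type="irreversible">
    <substrate id="103" name="cpd:C90003"/>
    <product id="104" name="cpd:C90004"/>
  </reaction>
  <reaction id="4" name="rn:R01714" type="irreversible">
    <substrate id="104" name="cpd:C90004"/>
    <product id="105" name="cpd:C90005"/>
  </reaction>
  <reaction id="5" name="rn:R01715" type="reversible">
    <substrate id="105" name="cpd:C90005"/>
    <product id="106" name="cpd:C90006"/>
  </reaction>
  <reaction id="6" name="rn:R02340" type="irreversible">
    <substrate id="106" name="cpd:C90006"/>
    <product id="107" name="cpd:C90007"/>
  </reaction>
  <reaction id="7" name="rn:R03508" type="irreversible">
    <substrate id="107" name="cpd:C90007"/>
    <product id="108" name="cpd:C90008"/>
  </reaction>
  <reaction id="8" name="rn:R03509" type="irreversible">
    <substrate id="107" name="cpd:C90007"/>
    <product id="108" name="cpd:C90008"/>
  </reaction>
  <reaction id="9" name="rn:R00674" type="irreversible">
    <substrate id="108" name="cpd:C90008"/>
    <product id="109" name="cpd:C90009"/>
  </reaction>
  <reaction id="10" name="rn:R01073" type="irreversible">
    <substrate id="106" name="cpd:C90006"/>
    <product id="110" name="cpd:C90010"/>
  </reaction>
  <reaction id="11" name="rn:R02722" type="irreversible">
    <substrate id="110" name="cpd:C90010"/>
    <product id="111" name="cpd:C90011"/>
  </reaction>
  <reaction id="12" name="rn:R00985" type="reversible">
    <substrate id="110" name="cpd:C90010"/>
    <product id="112" name="cpd:C90012"/>
  </reaction>
  <reaction id="13" name="rn:R00986" type="reversible">
    <substrate id="110" name="cpd:C90010"/>
    <product id="112" name="cpd:C90012"/>
  </reaction>
  <reaction id="14" name="rn:R03084" type="irreversible">
    <substrate id="112" name="cpd:C90012"/>
    <product id="113" name="cpd:C90013"/>
  </reaction>
  <reaction id="15" name="rn:R02413" type="irreversible">
    <substrate id="113" name="cpd:C90013"/>
    <product id="114" name="cpd:C90014"/>
  </reaction>
</pathway>
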