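<?xml version="1.0" encoding="UTF-8"?>
<!-- Builtin calculator registry. MW, N_O and NH_OH are computed by
     one program invocation and therefore share a progAggregateID. -->
<properties>
  <property name="MW" progAggregateID="PhysChem">
    <command>builtin:MW</command>
    <outputFields>MW</outputFields>
  </property>
  <property name="N_O" progAggregateID="PhysChem">
    <command>builtin:N_O</command>
    <outputFields>N_O</outputFields>
  </property>
  <property name="NH_OH" progAggregateID="PhysChem">
    <command>builtin:NH_OH</command>
    <outputFields>NH_OH</outputFields>
  </property>
  <property name="cLogP">
    <command>builtin:cLogP</command>
    <outputFields>cLogP</outputFields>
  </property>
  <property name="RotBonds">
    <command>builtin:RotBonds</command>
    <outputFields>RotBonds</outputFields>
  </property>
  <property name="RO5">
    <requiredCalculators>MW,cLogP,N_O,NH_OH</requiredCalculators>
    <keepRequiredCalculators>false</keepRequiredCalculators>
    <command>builtin:RO5</command>
    <outputFields>RO5</outputFields>
  </property>
</properties>
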