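<?xml version="1.0" encoding="UTF-8"?>
<!-- Pinned esskit dialect for Level-1 study_description.xml -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">
  <xs:element name="studyLevel1">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="title" type="xs:string"/>
        <xs:element name="description" type="xs:string"/>
        <xs:element name="essVersion" type="xs:string"/>
        <xs:element name="studyUuid" type="xs:string"/>
        <xs:element name="publications" type="xs:string"/>
        <xs:element name="pointOfContact" type="xs:string"/>
        <xs:element name="license" type="xs:string"/>
        <xs:element name="tasks">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="task" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="taskLabel" type="xs:string"/>
                    <xs:element name="description" type="xs:string"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="recordingParameterSets">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="recordingParameterSet" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="id" type="xs:string"/>
                    <xs:element name="modalities">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="modality" minOccurs="0" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:sequence>
                                <xs:element name="type" type="xs:string"/>
                                <xs:element name="startChannel" type="xs:integer"/>
                                <xs:element name="endChannel" type="xs:integer"/>
                                <xs:element name="samplingRate" type="xs:decimal"/>
                                <xs:element name="channelLabels">
                                  <xs:complexType>
                                    <xs:sequence>
                                      <xs:element name="channelLabel" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                                    </xs:sequence>
                                  </xs:complexType>
                                </xs:element>
                                <xs:element name="nonScalpChannelLabels">
                                  <xs:complexType>
                                    <xs:sequence>
                                      <xs:element name="channelLabel" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                                    </xs:sequence>
                                  </xs:complexType>
                                </xs:element>
                                <xs:element name="channelLocationType" type="xs:string"/>
                                <xs:element name="referenceLabel" type="xs:string"/>
                              </xs:sequence>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="sessions">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="session" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="number" type="xs:integer"/>
                    <xs:element name="taskLabel" type="xs:string"/>
                    <xs:element name="notes" type="xs:string"/>
                    <xs:element name="subjects">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="subject" minOccurs="0" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:sequence>
                                <xs:element name="labId" type="xs:string"/>
                                <xs:element name="group" type="xs:string"/>
                                <xs:element name="gender" type="xs:string"/>
                                <xs:element name="age" type="xs:string"/>
                                <xs:element name="hand" type="xs:string"/>
                                <xs:element name="height" type="xs:string"/>
                                <xs:element name="weight" type="xs:string"/>
                                <xs:element name="medication" type="xs:string"/>
                                <xs:element name="channelLocationFile" type="xs:string"/>
                              </xs:sequence>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="dataRecordings">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="dataRecording" minOccurs="0" maxOccurs="unbounded">
                            <xs:complexType>
                              <xs:sequence>
                                <xs:element name="uuid" type="xs:string"/>
                                <xs:element name="originalFileNameAndPath" type="xs:string"/>
                                <xs:element name="essFilename" type="xs:string"/>
                                <xs:element name="eventInstanceFilename" type="xs:string"/>
                                <xs:element name="parameterSetId" type="xs:string"/>
                                <xs:element name="startDateTime" type="xs:string"/>
                              </xs:sequence>
                            </xs:complexType>
                          </xs:element>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="eventCodeMappings">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="eventCodeMapping" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="taskLabel" type="xs:string"/>
                    <xs:element name="code" type="xs:string"/>
                    <xs:element name="categoryTag" type="xs:string"/>
                    <xs:element name="hedString" type="xs:string"/>
                    <xs:element name="description" type="xs:string"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="additionalMetadata" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:any processContents="skip" minOccurs="0" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
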